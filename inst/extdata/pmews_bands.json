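{
  "version": "1.0",
  "instrument": "PMEWS admission form, physiological grid",
  "comment": "Bands are stored as printed on the instrument: [lower, upper, sub-score], null = unbounded. Gaps between printed bands (e.g. SpO2 89) are closed at load time by extending the adjacent band with the higher sub-score.",
  "parameters": {
    "respiratory_rate": {
      "units": "breaths/min",
      "digits": 0,
      "plausible": [0, 80],
      "bands": [
        [null, 8, 3],
        [9, 18, 0],
        [19, 25, 1],
        [26, 29, 2],
        [30, null, 3]
      ]
    },
    "spo2": {
      "units": "%",
      "digits": 0,
      "plausible": [0, 100],
      "bands": [
        [null, 88, 3],
        [90, 93, 2],
        [94, 96, 1],
        [97, null, 0]
      ]
    },
    "heart_rate": {
      "units": "beats/min",
      "digits": 0,
      "plausible": [0, 250],
      "bands": [
        [null, 40, 3],
        [41, 50, 2],
        [51, 100, 0],
        [101, 110, 1],
        [111, 129, 2],
        [130, null, 3]
      ]
    },
    "systolic_bp": {
      "units": "mmHg",
      "digits": 0,
      "plausible": [0, 300],
      "bands": [
        [null, 70, 3],
        [71, 90, 2],
        [91, 100, 1],
        [101, null, 0]
      ]
    },
    "temperature": {
      "units": "degC",
      "digits": 1,
      "plausible": [25, 45],
      "bands": [
        [null, 35.0, 2],
        [35.1, 36.0, 1],
        [36.1, 37.9, 0],
        [38.0, 38.9, 1],
        [39.0, null, 2]
      ]
    }
  }
}
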