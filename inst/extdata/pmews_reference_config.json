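{
  "version": "1.0",
  "prevalence": 0.684,
  "latent": {
    "mu0": 0,
    "sigma0": 1,
    "mu1": 0.738339784437092,
    "sigma1": 1.08123001692412,
    "mu2": 3.65362143420375,
    "sigma2": 0.690735857018996,
    "q2": 0.295319352230134
  },
  "physio": {
    "respiratory_rate": {
      "slope": 0.343233364881025,
      "thresholds": [1.75458453524629, 17.376410505677, 18.9898241525882],
      "low_side_prob": 0.15
    },
    "spo2": {
      "slope": 1.89904608242801,
      "thresholds": [3.28609516483858, 4.23086227079246, 5.95983612928607]
    },
    "heart_rate": {
      "slope": 1.97611497945457,
      "thresholds": [2.47375341942839, 3.59213773718224, 5.36870373550081],
      "low_side_prob": 0.15
    },
    "systolic_bp": {
      "slope": 1.68327623816284,
      "thresholds": [2.83584513845006, 3.66752778870622, 5.89471368697951]
    },
    "temperature": {
      "slope": 1.37738170008657,
      "thresholds": [2.93190237264469, 3.82845215328342],
      "low_side_prob": 0.25
    },
    "consciousness": {
      "slope": 1.59533776614985,
      "thresholds": [3.15455456255605, 4.01804470492291, 6.15942109878328]
    }
  },
  "social": {
    "isolation": {
      "intercept": -7.10682975888123,
      "slope": 2.11639524096439
    },
    "chronic": {
      "intercept": -6.4058418665073,
      "slope": 3.57489207228371
    },
    "performance": {
      "slope": 3.27137594695199,
      "thresholds": [4.45469008966934, 104.80039729489, 14374.1459711523, 14438.0872826754]
    }
  },
  "age": {
    "mean": 39.8868211058559,
    "slope": 6.65334848422752,
    "sd": 28.0194214416347,
    "min": 12,
    "max": 100
  },
  "caps": {
    "respiratory_rate": [2, 60],
    "spo2": [60, 100],
    "heart_rate": [20, 200],
    "systolic_bp": [40, 250],
    "temperature": [30, 42]
  },
  "seed": null
}
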