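{
  "description": "Calibration report for the shipped reference generator configuration: staged derivative-free (Nelder-Mead) minimisation of the weighted mean squared relative deviation between achieved and target constraints, achieved values measured through the full simulate -> score -> ROC chain with common random numbers.",
  "note": "The calibrated configuration is one member of the family of generators consistent with the constraint targets; patient-level distributions are otherwise unidentified.",
  "weights_rationale": "The three characteristic-rate constraints are down-weighted because they are jointly inconsistent with the social-score mean under the instrument arithmetic; the discrimination constraints (PPV at cutoff 4, AUROCs) and component means are weighted up. See the methods vignette.",
  "objective_initial": 0.00218114533252461,
  "objective": 0.000811647125345957,
  "evaluations": 1842,
  "n_per_eval": 8000,
  "replicates": 4,
  "seeds": [62, 63, 64, 65],
  "free_blocks": ["latent", "physio", "performance", "isolation", "chronic", "age"],
  "constraints": [
    {
      "name": "prevalence",
      "target": 0.684,
      "weight": 1,
      "achieved_initial": 0.6778125,
      "achieved": 0.6778125,
      "rel_dev": -0.00904605263157897
    },
    {
      "name": "pmews_mean",
      "target": 2.71,
      "weight": 4,
      "achieved_initial": 2.81671875,
      "achieved": 2.70815625,
      "rel_dev": -0.000680350553505506
    },
    {
      "name": "pmews_sd",
      "target": 3.55,
      "weight": 0.5,
      "achieved_initial": 4.32743296172104,
      "achieved": 3.68260763626162,
      "rel_dev": 0.0373542637356685
    },
    {
      "name": "physio_mean",
      "target": 1.97,
      "weight": 2,
      "achieved_initial": 2.06246875,
      "achieved": 1.95228125,
      "rel_dev": -0.00899428934010153
    },
    {
      "name": "physio_sd",
      "target": 2.86,
      "weight": 0.5,
      "achieved_initial": 3.57411089826197,
      "achieved": 2.86160451864785,
      "rel_dev": 0.000561020506240306
    },
    {
      "name": "social_mean",
      "target": 0.75,
      "weight": 6,
      "achieved_initial": 0.75425,
      "achieved": 0.755875,
      "rel_dev": 0.00783333333333328
    },
    {
      "name": "social_sd",
      "target": 1.16,
      "weight": 0.5,
      "achieved_initial": 0.939348970065185,
      "achieved": 0.996878874492566,
      "rel_dev": -0.140621659920202
    },
    {
      "name": "age_mean",
      "target": 50.58,
      "weight": 1,
      "achieved_initial": 52.02396875,
      "achieved": 51.19403125,
      "rel_dev": 0.0121398032819297
    },
    {
      "name": "age_sd",
      "target": 22.15,
      "weight": 1,
      "achieved_initial": 22.359461559081,
      "achieved": 21.8225974409737,
      "rel_dev": -0.0147811539063797
    },
    {
      "name": "prop_over65",
      "target": 0.322,
      "weight": 0.1,
      "achieved_initial": 0.2938125,
      "achieved": 0.27421875,
      "rel_dev": -0.148388975155279
    },
    {
      "name": "prop_isolated",
      "target": 0.143,
      "weight": 0.1,
      "achieved_initial": 0.128625,
      "achieved": 0.13975,
      "rel_dev": -0.0227272727272726
    },
    {
      "name": "prop_chronic",
      "target": 0.525,
      "weight": 0.1,
      "achieved_initial": 0.31684375,
      "achieved": 0.30675,
      "rel_dev": -0.415714285714286
    },
    {
      "name": "ppv_at_cutoff4",
      "target": 0.976,
      "weight": 20,
      "achieved_initial": 0.973783211684271,
      "achieved": 0.970604542285837,
      "rel_dev": -0.00552813290385547
    },
    {
      "name": "auroc_total",
      "target": 0.738,
      "weight": 6,
      "achieved_initial": 0.720583259127315,
      "achieved": 0.716311833289483,
      "rel_dev": -0.0293877597703481
    },
    {
      "name": "auroc_physio",
      "target": 0.692,
      "weight": 4,
      "achieved_initial": 0.709410552604745,
      "achieved": 0.702336562802746,
      "rel_dev": 0.014937229483737
    },
    {
      "name": "auroc_social",
      "target": 0.667,
      "weight": 5,
      "achieved_initial": 0.686960946238805,
      "achieved": 0.686464100471559,
      "rel_dev": 0.0291815599273751
    }
  ]
}
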