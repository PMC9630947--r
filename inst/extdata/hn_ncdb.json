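{
  "comment": "Synthetic head-and-neck-like registry preset. Marginals echo a published cohort (n = 4042, treated fraction 0.63, cancer-site split ~50.9/35.9/13.2 after renormalizing printed CMT fractions). The treatment model and covariate joint distribution are synthetic: covariates independent, intercept calibrated by Monte Carlo so the mean true propensity is 0.63.",
  "n": 4042,
  "seed": 101,
  "covariates": [
    {"name": "age", "kind": "continuous", "lo": 71, "hi": 90, "mean": 77, "sd": 6, "integer": true},
    {"name": "sex", "kind": "categorical", "levels": ["Male", "Female"], "probs": [0.675, 0.325]},
    {"name": "race", "kind": "categorical", "levels": ["White", "Black", "Other"], "probs": [0.854, 0.123, 0.023]},
    {"name": "comorbidity", "kind": "categorical", "levels": ["0", "1", "2"], "probs": [0.712, 0.203, 0.085]},
    {"name": "site", "kind": "categorical", "levels": ["larynx", "oropharynx", "hypopharynx"], "probs": [0.509090909090909, 0.358585858585859, 0.132323232323232]},
    {"name": "tstage", "kind": "categorical", "levels": ["T1", "T2", "T3", "T4"], "probs": [0.067, 0.229, 0.444, 0.26]},
    {"name": "nstage", "kind": "categorical", "levels": ["N0", "N1", "N2", "N3"], "probs": [0.39, 0.24, 0.34, 0.03]}
  ],
  "treatment_coefficients": [11.953609, -0.15, 0, 0, 0, -0.1, -0.3, 0.3, 0.2, 0, 0, 0.2, 0.2, 0.6, 0.6]
}
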