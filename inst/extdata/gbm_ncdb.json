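{
  "comment": "Synthetic glioblastoma-like registry preset for the combined-modality vs radiation-alone pairwise comparison of a three-arm design (n = 10128, treated fraction 0.8328). Adds surgery and year-of-diagnosis covariates. Covariates independent; age truncated-normal approximates the printed age-category fractions; intercept calibrated by Monte Carlo to the treated fraction.",
  "n": 10128,
  "seed": 102,
  "covariates": [
    {"name": "age", "kind": "continuous", "lo": 65, "hi": 90, "mean": 59, "sd": 14, "integer": true},
    {"name": "sex", "kind": "categorical", "levels": ["Female", "Male"], "probs": [0.558, 0.442]},
    {"name": "race", "kind": "categorical", "levels": ["White", "Black", "Other"], "probs": [0.931, 0.04, 0.029]},
    {"name": "comorbidity", "kind": "categorical", "levels": ["0", "1", "2"], "probs": [0.689, 0.195, 0.116]},
    {"name": "year", "kind": "categorical", "levels": ["2005-2008", "2009-2011"], "probs": [0.528, 0.472]},
    {"name": "surgery", "kind": "categorical", "levels": ["No", "Yes"], "probs": [0.255, 0.745]}
  ],
  "treatment_coefficients": [6.638594, -0.08, 0, 0, 0, 0, -0.2, 0.3, 1.2]
}
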