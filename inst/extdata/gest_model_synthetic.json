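{
  "name": "synthetic-placeholder",
  "comment": "Synthetic stand-in specification: clinically plausible effect directions and magnitudes on the GEST covariate set. NOT the published derivation-study coefficients; replace this file with a transcription of those values to score with the real model.",
  "intercept": -2.6,
  "covariates": [
    {"name": "age",                         "imputation": 77,   "mean": 77,   "sd": 8,    "coefficient": 0.45,  "standardize": true},
    {"name": "hemoglobin",                  "imputation": 12.5, "mean": 12.5, "sd": 1.8,  "coefficient": -0.20, "standardize": true},
    {"name": "hematocrit",                  "imputation": 37.5, "mean": 37.5, "sd": 5.6,  "coefficient": -0.05, "standardize": true},
    {"name": "blood_urea_nitrogen",         "imputation": 18,   "mean": 20,   "sd": 9.5,  "coefficient": 0.35,  "standardize": true},
    {"name": "red_cell_distribution_width", "imputation": 14.2, "mean": 14.2, "sd": 1.8,  "coefficient": 0.40,  "standardize": true},
    {"name": "lymphocyte_count",            "imputation": 1.5,  "mean": 1.5,  "sd": 0.65, "coefficient": -0.15, "standardize": true},
    {"name": "mean_corpuscular_volume",     "imputation": 90,   "mean": 90,   "sd": 5.5,  "coefficient": 0.10,  "standardize": true},
    {"name": "mean_heart_rate",             "imputation": 84,   "mean": 84,   "sd": 13,   "coefficient": 0.25,  "standardize": true},
    {"name": "min_systolic_bp",             "imputation": 127,  "mean": 127,  "sd": 19,   "coefficient": -0.30, "standardize": true},
    {"name": "supplemental_oxygen",         "imputation": 0,    "mean": 0,    "sd": 1,    "coefficient": 0.90,  "standardize": false},
    {"name": "admissions_past_year",        "imputation": 0,    "mean": 0.7,  "sd": 1.1,  "coefficient": 0.30,  "standardize": true},
    {"name": "dx_secondary_cancer",         "imputation": 0,    "mean": 0,    "sd": 1,    "coefficient": 1.30,  "standardize": false},
    {"name": "dx_cognitive_disorder",       "imputation": 0,    "mean": 0,    "sd": 1,    "coefficient": 0.50,  "standardize": false},
    {"name": "dx_lung_cancer",              "imputation": 0,    "mean": 0,    "sd": 1,    "coefficient": 1.10,  "standardize": false},
    {"name": "dx_pancreatic_cancer",        "imputation": 0,    "mean": 0,    "sd": 1,    "coefficient": 1.50,  "standardize": false},
    {"name": "ed_dx_syncope_or_cva",        "imputation": 0,    "mean": 0,    "sd": 1,    "coefficient": 0.30,  "standardize": false},
    {"name": "outpatient_cv_meds",          "imputation": 1,    "mean": 0,    "sd": 1,    "coefficient": 0.15,  "standardize": false}
  ]
}
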