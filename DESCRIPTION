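Package: gestval
Title: External Validation of an Emergency-Department Six-Month Mortality
    Screening Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to externally validate the Geriatric End-of-Life
    Screening Tool (GEST), a logistic regression score estimating 6-month
    mortality for emergency-department patients aged 65 or older.  Provides
    a declarative risk-model engine (median imputation, standardization,
    logistic prediction), feature extraction from encounter-linked vitals,
    labs, diagnoses and admissions tables, ICD-10 serious-illness flagging
    with a 1-year lookback, DeLong AUROC confidence intervals, calibration
    tables, intercept recalibration and full refitting on a temporal split,
    screening test characteristics with confidence intervals, decision-curve
    net benefit, Kaplan-Meier survival with administrative right-censoring,
    and a seeded synthetic ED cohort generator so the whole pipeline runs
    and is testable without access to protected health records.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
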