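Package: rdrisk
Title: External Validation of Risk Prediction Models for Referable
    Diabetic Retinopathy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for externally validating prognostic models that predict
    progression to referable diabetic retinopathy (RDR) in longitudinal
    screening cohorts.  Implements the English screening-programme R/M
    grading logic and two-screening risk-group classification, cohort
    construction from raw screening and systemic-visit streams, a
    configurable survival-based risk-score engine (proportional-hazards
    scores with exponential, Weibull or tabulated baseline survival, plus
    grade-category score models), time-dependent ROC discrimination with
    inverse-probability-of-censoring weights and bootstrap confidence
    intervals, risk-stratified person-years incidence tables, and a
    seeded synthetic cohort generator with known ground-truth risk
    structure for end-to-end testing and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
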