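Package: exposomeRF
Title: Random-Forest Identification of Longitudinal Exposome Predictors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A six-step machine-learning pipeline for identifying
    longitudinal exposome predictors of a binary health outcome in
    cohort studies with repeated exposure measurements. Repeated
    exposures are summarized per subject as the Area-Under-the-Exposure
    (AUE, the time-averaged exposure level) and the Trend-Of-the-Exposure
    (TOE, the average slope between consecutive measurement rounds); a
    tuned random forest predicts the outcome from these summaries;
    predictors are ranked by out-of-bag permutation importance (mean
    decrease in accuracy); the number of retained predictors is chosen
    from a cross-validated AUC curve; and exposure-outcome relations are
    visualized with partial dependence and accumulated local effects
    curves. Includes a synthetic longitudinal cohort generator with
    planted effects and known ground truth so every pipeline stage can
    be validated without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    randomForest,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils,
    tools
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
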