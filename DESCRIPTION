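Package: ihdforest
Title: Balanced Random Forest Prediction of Intraoperative Hemodynamic
    Instability in Pheochromocytoma Surgery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for predicting intraoperative hemodynamic
    instability (IHD) during pheochromocytoma resection from routine clinical
    predictors. Provides a synthetic-cohort generator matching the published
    population summaries of the study cohort, Relief-F feature weighting with
    threshold-based retention, a benchmark harness over hold-out,
    cross-validation and bootstrap validation schemes, a balanced random
    forest (an ensemble of random forests each trained on class-balanced
    bootstrap resamples, combined by sign voting) for the imbalanced outcome,
    confusion-matrix and ROC/AUC model assessment, and permutation (MDA) and
    Gini (MDG) variable importance with a cross-ranking consensus rule for the
    final risk-factor set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    randomForest,
    rpart,
    e1071,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
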