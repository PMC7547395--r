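Package: cdistrat
Title: Case-Difficulty Scoring and Difficulty-Stratified Classifier Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scores the classification difficulty of individual cases in a
    tabular clinical cohort with a two-parameter logistic (2PL) item response
    theory model fitted to dichotomized feature indicators, and evaluates
    machine-learning classifiers stratified by difficulty instead of by a
    single scalar metric. Provides cohort coding (normal-range
    dichotomization, chained-equation imputation, balanced/imbalanced
    sampling designs), marginal maximum likelihood 2PL estimation with
    expected-a-posteriori case scoring, a six-classifier cross-validation
    bench with per-case prediction tracking, difficulty-binned accuracy
    reports with fixed-effects logistic interaction tests, and a synthetic
    intensive-care-style cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    rpart,
    nnet,
    e1071,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    emmeans,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
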