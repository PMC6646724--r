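Package: mciprognosis
Title: Site-Independent Ensemble Prognosis of Conversion from Mild
    Cognitive Impairment to Alzheimer's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits and evaluates a weighted rank-average ensemble of
    supervised learners that predicts 3-year conversion from mild
    cognitive impairment (MCI) to Alzheimer's disease from
    sociodemographic, clinical and neuropsychological tabular features.
    Implements a full site-independent validation protocol: a
    stratified partition of recruitment sites into five mutually
    exclusive test subsets, train-fitted preprocessing (median/mode
    imputation, standardization, one-hot encoding, correlation-group
    principal-component substitution), four feature-selection
    strategies, repeated stratified cross-validation with random plus
    Gaussian-process Bayesian hyper-parameter search over thirteen
    learning techniques, rank-based ensembling weighted by
    cross-validated AUROC, sensitivity-targeted threshold calibration,
    pooled test evaluation with stratified BCa bootstrap confidence
    intervals, and single-feature importance ranking. A synthetic
    multi-site cohort generator reproducing published class-conditional
    summary statistics makes the whole pipeline exercisable without
    access-restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    class,
    e1071,
    glmnet,
    randomForest,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    boot,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
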