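Package: ppgdm
Title: Postpartum Prediabetes Risk Prediction After Gestational Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis workflow for predicting postpartum prediabetes in
    women diagnosed with gestational diabetes mellitus from routinely
    collected antenatal variables. Implements outcome labelling under NICE,
    WHO and ADA glycaemic criteria; a seeded synthetic-cohort generator
    emulating the antenatal and postpartum characteristics of a GDM audit
    cohort; leakage-safe fold-local preprocessing (chained-equations
    imputation, standardisation, balanced class weights); nested
    cross-validation (leave-one-out or stratified k-fold outer, stratified
    inner) for L1-penalised class-weighted logistic regression and tree
    ensembles; a two-variable composite risk score; Kullback-Leibler
    divergence cut-point selection with rule-in/rule-out diagnostics,
    information graphs and the Bregman-divergence representation; decision
    curve analysis; and two-sample power analysis via the noncentral t
    distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    rpart,
    randomForest,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
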