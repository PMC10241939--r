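Package: metsflow
Title: Metabolic Syndrome Risk Prediction from Longitudinal Exam Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for one-year-ahead metabolic syndrome (MetS) risk
    prediction from five consecutive years of physical-examination records:
    guideline-based MetS labeling (Chinese 2017 T2DM guideline, three-of-five
    rule), cohort cleaning and imputation, construction of prediction windows
    (four healthy input years plus a label year), sigmoid-weighted temporal
    delta features (differential fluctuant features, DFFs) alongside plain
    year-to-year numeric and state differences, cross-validated classifier
    benchmarking (XGBoost, random forest, stacking, logistic regression), and
    stratified odds-ratio and prevalence analysis by sex and age group. A
    synthetic-cohort generator with published sex-specific marginals, planted
    within-subject autocorrelation and a drifting (incident-MetS)
    subpopulation makes every stage testable without access to hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
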