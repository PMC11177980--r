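Package: acsselect
Title: Selective Classification with Ensemble Uncertainty for Prehospital ACS Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to study uncertainty-aware selective classification for
    acute coronary syndrome (ACS) prediction from prehospital tabular
    covariates. Provides a synthetic chest-pain cohort generator calibrated
    to published covariate marginals and outcome prevalences, an ensemble of
    gradient-boosted tree classifiers with entropy-based decomposition of
    predictive uncertainty into data and model components, a validation-quantile
    abstention rule, rule-based HEAR/HEART score comparators, and a stratified
    cross-validation evaluation protocol with coverage-constrained metrics,
    ablations and risk-coverage curves.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
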