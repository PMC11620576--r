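Package: iganclaims
Title: Computable Phenotyping of IgA Nephropathy from Medical Billing Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies patients diagnosed with IgA nephropathy (IgAN) purely
    from structured medical billing data. Provides parsing and hierarchical
    grouping of Japanese MHLW 12-character drug codes and ICD-10 diagnosis
    codes, rule-based diagnostic criteria with full 2x2 performance metrics
    (sensitivity, specificity, predictive values, accuracy), a factor-count
    manual score with ROC/AUC and Youden cutoff analysis, and a stratified
    5-fold cross-validated gradient-boosted classifier with seeded random
    hyperparameter search and split-count feature importances. A synthetic
    claims-cohort generator and a deterministic fixture emulate the marginal
    structure of a single-center nephrology cohort (437 IgAN and 3,306
    non-IgAN patients), standing in for hospital data that cannot be
    deposited.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xgboost
Suggests:
    pROC,
    yaml,
    withr,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
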