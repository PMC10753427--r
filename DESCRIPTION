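Package: medscreen
Title: Medication-Wide Screening for Early-Onset Cancer Risk in Matched
    Case-Control Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for hypothesis-free pharmacoepidemiologic screening of
    dispensing records in a density-matched (risk-set) case-control design.
    Provides a synthetic electronic-medical-record generator with planted
    conditional medication effects and confounding by indication; case
    ascertainment, exclusion, and 1:M risk-set matching; construction of
    lagged ever/never exposure matrices at ATC level 5 with rare-drug
    filtering; a consensus feature screen based on repeated gradient-boosted
    tree models with Bayesian hyperparameter optimization and global Shapley
    importances; and a from-scratch conditional logistic regression for
    matched sets yielding adjusted odds ratios with Wald confidence
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    Matrix,
    xgboost (>= 1.7),
    lhs,
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    optparse,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
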