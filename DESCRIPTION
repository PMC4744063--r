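Package: hybridsel
Title: Hybrid Variable Selection for Binary Outcomes in Complex Surveys
    with Missing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Three-step variable selection for binary health outcomes
    measured in complex-survey epidemiological studies with missing
    predictor data. Step 1 diagnoses the missingness mechanism
    (missing-indicator regressions, Little's MCAR test) and performs
    multiple imputation by chained equations. Step 2 runs stochastic
    gradient-boosted regression trees (Bernoulli loss, shrinkage,
    bagging, validation-based stopping) on the original and each imputed
    dataset and applies a relative-importance inclusion cutoff. Step 3
    confirms candidates with design-based (Taylor-linearized) logistic
    regression pooled across imputations by Rubin's rules, including
    univariate screening on train/validation halves, collinearity and
    mediation elimination, a confounder-and-interaction final model, and
    a design-adjusted goodness-of-fit F test. Includes validation
    baselines (backward stepwise selection, L1-penalized selection
    frequency) and a survey-structured synthetic-data generator with
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
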