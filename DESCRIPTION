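Package: coarselur
Title: Spatial Prediction Models for Coarse Particulate Matter from Snapshot Campaigns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds land-use-regression (LUR) and universal-kriging (UK) spatial
    prediction models for coarse particulate matter (PM10-2.5) mass and chemical
    components from short-term "snapshot" monitoring campaigns. Implements the
    full modelling pipeline: sample quality control and PM10 - PM2.5 subtraction,
    geographic-covariate screening (variability filter, best short/long buffer
    selection, correlation pruning), LASSO shortlisting followed by exhaustive
    best-subset search with season and city interactions, 10-fold cross-validated
    RMSE/R-squared model selection, exponential-variogram fitting with simple
    kriging of regression residuals, city-stratified evaluation metrics with
    zero-truncated per-city R-squared, and stratified/pooled campaign summary
    statistics. A synthetic-campaign generator with known ground truth (sparse
    linear signal over nested buffered covariates, exponential-covariance spatial
    residuals, injected quality-control defects) makes every stage testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
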