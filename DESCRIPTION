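Package: fnirselect
Title: Exhaustive Channel-Subset Selection for Two-Group fNIRS Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies two-group multichannel functional near-infrared
    spectroscopy (fNIRS) oxy-hemoglobin trial data by exhaustive wrapper
    feature selection over measurement channels. Raw per-trial time series
    are band-pass filtered, standardized to baseline Z-scores, and reduced
    to per-channel mean-Z features; every nonempty channel subset is then
    scored with a linear maximum-margin classifier under stratified K-fold
    cross-validation, and subsets are ranked by cross-validation error with
    weight-sign interpretation. Embedded sparse baselines (LASSO and an
    L1-penalized sparse logistic regression) and channel-wise t-tests with
    Benjamini-Hochberg false-discovery-rate correction are included for
    comparison, together with a synthetic hemodynamic trial simulator with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
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
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
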