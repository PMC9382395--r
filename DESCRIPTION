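Package: imbcalib
Title: Class Imbalance Corrections and the Calibration of Risk Prediction Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how class-imbalance corrections (random
    undersampling, random oversampling, SMOTE) affect clinical risk
    prediction models based on standard and ridge-penalized logistic
    regression. Provides a calibrated synthetic data generator for
    binary-outcome prediction settings, the three resampling corrections,
    model fitting with optional restricted cubic splines and intercept
    recalibration, a full set of test-set performance metrics
    (discrimination, calibration intercept and slope, flexible calibration
    curves, classification, Net Benefit and decision curves), and a Monte
    Carlo simulation engine that runs factorial scenario grids and
    summarizes per-method performance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
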