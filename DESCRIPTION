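Package: ansacuity
Title: Diffusion-Model Estimation of Approximate Number System Acuity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the acuity of the approximate number system (ANS)
    from trial-level numerosity-comparison data using a drift-diffusion
    model in which the drift rate for each ratio condition is the
    log-numerosity difference multiplied by a participant-level drift
    scale. Parameters (boundary separation, starting-point range, drift
    scale, across-trial drift variability, non-decision time and its
    range, contaminant proportion) are estimated by the chi-square
    quantile method. Also provides the classical log-scale Weber-fraction
    model fitted to ratio-wise accuracy, a trial-level study simulator
    with cohort heterogeneity and correlated math scores, and
    cohort-level analyses: split-half reliability with Spearman-Brown
    correction, dependent-correlation (Steiger) tests, regression with
    covariates, inverse efficiency scores, trial-subset reliability
    curves, and half-cohort resampling.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
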