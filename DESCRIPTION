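Package: thermentropy
Title: Multiscale Entropy Analysis of Skin-Temperature Time Series for
    Pressure-Injury Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the complexity of 1-minute skin-temperature
    recordings from wearable thermochron loggers and relating it to
    pressure-injury status.  Implements refined multiscale sample entropy and
    bubble entropy with Butterworth low-pass coarse-graining, summary
    statistics of the entropy-versus-scale curve (a log-scale scaling exponent
    and a windowed area under the curve) with effect-size-optimised scale
    ranges, per-scale Welch group contrasts, noncentral-t power calculations,
    and entropy-based prediction of injury status via adaptive-lasso logistic
    regression and a compact two-node neural classifier.  A synthetic cohort
    generator reproduces the statistical structure of logger recordings
    (circadian rhythm, autoregressive noise, 11-bit quantisation, sensor
    on/off ambient tails) so the whole pipeline can be exercised end to end
    without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    glmnet,
    signal,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
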