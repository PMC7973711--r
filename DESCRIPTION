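Package: affectdyn
Title: Continuous- and Discrete-Time Models of Affect Dynamics from
    Experience-Sampling Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits and compares the continuous-time Ornstein-Uhlenbeck (OU)
    model, the discrete-time lag-1 vector autoregressive (VAR(1)) model and a
    stationary Gaussian model on irregularly spaced experience-sampling (ESM)
    affect time series. Includes measurement-error variants via linear Gaussian
    state-space models with Kalman-filter marginal likelihoods, differential
    evolution maximum-likelihood estimation, walk-forward out-of-sample
    cross-validation of one-step predictive accuracy, removal of large
    abrupt changes by a median + C*MAD rule on normalized change speeds, and a
    synthetic ESM study generator (stratified random beep schedules, latent OU
    dynamics, event-driven jumps, measurement error, missingness) so the whole
    pipeline is testable without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
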