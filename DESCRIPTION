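Package: impulsets
Title: Impulsive Time-Series Estimation for Pulsatile Hormone Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint estimation of a sparse train of instantaneous secretion
    impulses and the two elimination rates of a second-order linear hormone
    cascade from sampled, noisy concentration measurements (e.g. pulsatile
    luteinizing hormone or cortisol profiles). Implements a non-negative
    least-squares estimator of the feasibility-boundary curve in the
    elimination-rate plane via a Newton-step tangent construction, with
    impulse-train sparsification by thresholding, constrained refitting and
    moment-matched merging; an adaptive Metropolis sampler of the joint
    posterior over impulse times, weights and elimination rates with
    Gelman-Rubin convergence gating; diagnostics comparing the posterior
    cloud with the estimated curve; and a seeded generator of synthetic
    impulsive time series emulating luteinizing-hormone-like and
    cortisol-like sampling protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
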