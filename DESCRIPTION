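Package: dcmprofile
Title: Profile-Likelihood Identifiability Analysis for Dynamic Causal
    Models of fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates blood-oxygen-level-dependent (BOLD) time series from
    deterministic bilinear dynamic causal models (DCM) of effective
    connectivity, estimates all connectivity parameters by maximum
    likelihood (Levenberg-Marquardt weighted least squares), computes each
    parameter's profile likelihood and likelihood-based confidence
    interval, classifies parameters as identifiable, practically
    non-identifiable or structurally non-identifiable, and scores whole
    acquisition designs with the mean confidence-interval (A-optimality)
    criterion across variations of repetition time, session duration,
    epoch duration and signal-to-noise ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
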