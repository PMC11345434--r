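Package: hopfec
Title: Generative Effective Connectivity from Coupled Hopf Oscillator Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring directed (effective) connectivity between brain
    regions from parcellated electrophysiological time series using a generative
    whole-brain model of coupled Stuart-Landau (Hopf) oscillators. The package
    simulates the oscillator network, computes empirical functional connectivity
    and time-lagged normalised covariance matrices, derives the model moments in
    closed form from a linearisation (Lyapunov stationary covariance and a
    matrix-exponential lag), and estimates an asymmetric coupling matrix by a
    pseudo-gradient fit in either a simulation-based or an analytic mode. It also
    provides the downstream analyses used with such fits: directional contrasts
    between region sets tested with paired t-tests across participants,
    symmetrised and asymmetry views of the coupling matrix, display and
    density-matched thresholds, hemispheric laterality differences, and a
    synthetic multi-participant cohort generator with known directed ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    generics,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
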