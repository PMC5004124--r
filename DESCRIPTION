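Package: sleepreplay
Title: Bayesian Population Decoding and Replay Detection for Hippocampal
    Ensemble Spike Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing hippocampal place-cell population activity
    at sleep-like timescales. Implements two Bayesian population decoders: a
    supervised decoder built on occupancy-normalised receptive fields with a
    Poisson spike-count likelihood, and an unsupervised hierarchical
    Dirichlet process hidden Markov model (HDP-HMM) with Poisson emissions
    whose state number is inferred by Gibbs sampling. Includes a synthetic
    place-cell data generator with sleep-like transformations (epoch
    splitting with random reversal, cell subsampling, spike thinning,
    non-place-cell injection), spatial information rates, sharp-wave-ripple
    candidate-event screening from multi-unit activity, and shuffle-based
    replay significance testing via the weighted correlation and its
    Z-score, together with a Monte Carlo experiment harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
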