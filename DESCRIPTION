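Package: rhythmsim
Title: Temporal Prediction in Jittered Tone Sequences: Stimuli, Psychometrics,
    Adaptive-Frequency Oscillator and Bayesian Observer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates psychophysical experiments on temporal prediction in
    quasi-rhythmic tone sequences and the two model families proposed to
    explain them. Generates jittered tone-sequence stimuli, scores early/late
    probe judgments against absolute (duration-based) and relative
    (rhythm-based) timing predictions, fits logistic psychometric functions
    with chi-square exclusion and rotated-axes dominance-curve analysis,
    integrates a Wilson-Cowan neural mass model with an adaptive tonic input
    that retunes its natural frequency near a SNIC bifurcation, and implements
    a Bayesian ideal observer with Gaussian fusion and duration- or
    rhythm-based priors. All figure-level quantities are regenerable from
    synthetic data under fixed seeds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
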