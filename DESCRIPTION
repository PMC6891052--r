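Package: rhythmgain
Title: Rhythmic Temporal Expectation and Neural Gain in Auditory M/EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of how rhythmic temporal expectation
    modulates auditory neural processing. Generates tone/chord stimulus
    sequences and synthetic multichannel M/EEG with known ground truth;
    implements Mahalanobis-distance decoding of tone frequency and chord
    identity with Ledoit-Wolf shrinkage covariance, phase-locking (inter-trial
    coherence) analysis with a fixed-window Morlet transform, a gain/tuning
    population model with AIC-based random-effects Bayesian model selection,
    cluster-based permutation inference, and signal-detection behavioral
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    arrow,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
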