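Package: paircnn
Title: Minimal-Electrode Motor-Imagery EEG Decoding with a Separated
    Temporal-Spatial Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decodes four-class motor-imagery EEG from single symmetric
    electrode pairs using raw signals and a compact convolutional network
    with separated temporal and spatial filters, spatial dropout and batch
    normalization.  Provides EDF+ reading with cue-annotation epoching,
    construction of 640 x 2 electrode-pair samples, trial-wise 10-fold
    cross-validation, a from-scratch trainable network with Adam
    optimisation, a full metric suite (confusion matrix, precision, recall,
    F-score, one-vs-rest ROC/AUC), and a synthetic generator of
    event-related-desynchronization epochs so the whole pipeline is
    exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
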