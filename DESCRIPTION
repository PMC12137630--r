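Package: neodev
Title: Developmental Two-Photon Imaging Analysis: Population Events, Sleep
    States, Decoding and Input Maps
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for developmental two-photon calcium and
    serotonin-sensor imaging of neonatal mouse cortex. Provides delta-F/F
    normalisation (mean-baseline and first-percentile variants), detection
    and classification of high-/low-synchronicity population calcium events,
    pairwise correlation structure and stimulus-response statistics with
    Shapiro-Wilk-gated paired testing and Benjamini-Hochberg correction,
    sleep-state scoring from pose-tracking movement, permutation-calibrated
    logistic-regression population decoding with subject-wise
    cross-validation, and laser-scanning photostimulation (LSPS) input-map
    analysis with postsynaptic-current feature extraction. A synthetic-data
    generator with known ground truth makes every stage verifiable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    yaml,
    jsonlite,
    data.table,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
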