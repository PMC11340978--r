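Package: stertor
Title: Detection and Grading of Stertor in Canine Laryngeal Stethoscope Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting and grading stertor (the
    low-frequency obstructive breathing sound characteristic of brachycephalic
    obstructive airway syndrome, BOAS) in laryngeal electronic-stethoscope
    recordings of dogs. Provides WAV audio handling, Hann-window spectrogram
    feature extraction clipped to the 20-400 Hz stethoscope band, a
    bidirectional gated recurrent network with self-attentive pooling trained
    as an ordinal (cumulative-target) regression, per-encounter aggregation of
    recording predictions into a BOAS classification, a nested
    cross-validation protocol with covariate-balanced (stratified
    minimisation) fold assignment, ROC analysis with vertical averaging, and a
    seeded synthetic audio-cohort generator so the whole pipeline can be
    exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    graphics,
    grDevices,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
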