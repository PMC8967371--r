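Package: eegstn
Title: Spatiotemporal Neural Network Pipeline for EEG Emotion Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for cross-subject and cross-database
    EEG emotion recognition with a spatiotemporal neural network. Provides
    FIR band-pass preprocessing and epoching, unsupervised Euclidean
    alignment (whitening by the inverse square root of each subject's mean
    spatial covariance), time-frequency band-energy features via the
    short-time Fourier transform and the Hilbert-Huang transform (empirical
    mode decomposition plus Hilbert spectrum), montage-aware mapping of
    channel features onto a 2D electrode-topology grid, and a cascaded
    2D-CNN + bidirectional LSTM classifier trained with SGD, together with
    cross-database, leave-one-subject-out and subject-stratified k-fold
    evaluation protocols. A synthetic multi-subject EEG generator with
    known band-power structure and per-subject covariance shift makes the
    whole pipeline testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
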