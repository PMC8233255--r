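Package: swrnet
Title: Sharp-Wave Ripple Detection in LFP Recordings with Recurrent Neural
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects hippocampal sharp-wave ripple (SPW-R) events in
    single-channel local field potential (LFP) recordings with a trainable
    recurrent sequence-labeling network (1D convolutions feeding uni- or
    bidirectional LSTM layers with a time-distributed sigmoid readout),
    implemented from scratch with full backpropagation through time and Adam
    optimization. Also provides the conventional Hilbert-envelope
    adaptive-threshold detector used for manual curation workflows, a
    synthetic pink-noise LFP generator with ground-truth ripple events,
    complex Morlet wavelet spectrograms, thresholded peak detection with
    grid-search tuning, chunked median prediction on time-continuous signals,
    and event-level precision/recall/F1, cross-correlogram and signal-energy
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics,
    rhdf5,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
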