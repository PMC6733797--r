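Package: eegtrack
Title: Continuous EEG-Based Tracking of Sedation Level and Delirium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for continuous tracking of level of consciousness
    (Richmond Agitation-Sedation Scale, RASS -5..0) and delirium
    (CAM-ICU probability) from frontal EEG. Implements bipolar
    re-referencing of the Fp1/F7/Fp2/F8 montage, notch/bandpass
    filtering with downsampling to 62.5 Hz, 4-s epoching, rule-based
    artifact rejection, spectral band-power and burst-suppression-ratio
    features, a convolutional encoder with stacked LSTM layers and an
    ordinal-regression (cumulative-link) z-score head trained in
    stages, transfer of early convolutional blocks to a binary
    delirium head, evaluation metrics (balanced MAE, tolerance
    accuracy, coma-vs-awake AUC, probability calibration), rater
    agreement pairing, a tracking-delay experiment, gradient saliency
    maps, and a seeded synthetic frontal-EEG generator with
    state-dependent spectra and injectable artifacts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
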