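Package: chtlm
Title: Cross-Subject Heterogeneous EEG-to-fNIRS Transfer Learning for
    Motor-Imagery Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies motor imagery versus rest from functional
    near-infrared spectroscopy (fNIRS) recordings by transferring knowledge
    from an EEG-trained convolutional source encoder into a lighter fNIRS
    target encoder through an adaptive feature-matching network. Provides
    modified Beer-Lambert conversion of dual-wavelength optical intensities
    to oxy-/deoxyhemoglobin concentration changes, zero-phase band-pass
    filtering, trial segmentation, wavelet and short-time-Fourier
    time-frequency images, residual convolutional encoders with per-stage
    feature taps, a weighted feature-matching transfer loss with learned
    per-kernel transfer weights, Mann-Whitney U feature filtering, a sparse
    Bayesian extreme learning machine classifier, leave-one-subject-out
    evaluation, and a synthetic EEG/fNIRS trial generator so that every
    stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
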