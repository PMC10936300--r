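Package: sonomoment
Title: Ankle Joint Moment Prediction from Muscle Ultrasound Image Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for predicting the ankle net plantarflexion
    moment during treadmill walking from brightness-mode (B-mode) ultrasound
    image sequences of the plantarflexor muscles. Includes plane-wave
    delay-and-sum beamforming of raw radio-frequency channel data, envelope
    detection and log compression, physical-coordinate region-of-interest
    cropping, ground-reaction-force based stance-phase segmentation, surface
    EMG scalogram (continuous wavelet transform) spectrum imaging for the
    comparative electromyography route, a 31-layer convolutional neural
    network regressor trained per subject with leave-one-speed-out
    cross-validation, the associated evaluation metrics (regression loss,
    RMSE, normalized RMSE, coefficient of determination, linear agreement)
    and normality-gated statistical comparisons, plus a seeded synthetic
    multi-speed walking-data generator so that every stage is testable
    without access to motion-lab recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    emmeans,
    tibble,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
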