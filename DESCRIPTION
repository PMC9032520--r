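Package: gazeauth
Title: Gaze-Based Biometric Authentication from Short Eye-Movement Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for verifying identity from short (5-12 s)
    monocular eye-movement recordings. Converts gaze angles to screen
    coordinates, classifies fixations and saccades with a velocity-threshold
    (I-VT) algorithm, quantifies attention decay over recording time via the
    distraction angle relative to the 1-degree foveal radius, extracts
    spatiotemporal features (per-step motion information channels and saccade
    distribution maps), embeds them with a two-branch convolutional network
    trained by deep metric learning (multi-similarity loss for open-set,
    additive angular margin loss for closed-set), and evaluates verification
    performance with genuine/imposter pairing, ROC curves and the equal error
    rate. Includes a 1000 Hz synthetic gaze simulator with per-subject
    oculomotor signatures so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
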