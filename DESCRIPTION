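Package: phenogaze
Title: Gaze and Emotion-Response Phenotyping Pipelines for Autism Research
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for wearable eye-tracking studies of facial attention and
    emotion recognition in children. Provides a synthetic session generator
    (cohorts with latent distraction propensities, balanced stimulus
    schedules, Markov gaze streams, drifting pupil-to-screen calibration
    epochs, and emotion responses with confusion structure), pupil-center
    detection from eye-camera frames (stable extremal regions, a
    means-of-gradients objective, and window-based optical flow, with a
    gated fusion rule), per-epoch polynomial gaze calibration validated
    against on-screen dot events, area-of-interest frame coding with
    distraction-ratio statistics and one-tailed group tests, construction of
    confusion-matrix, response-correctness, gaze-pattern and metadata
    feature families, and elastic-net classification evaluated with
    leave-one-participant-out cross-validation and Monte Carlo label-shuffle
    significance tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    glmnet,
    jsonlite,
    generics,
    stats,
    utils,
    withr,
    Rcpp,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
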