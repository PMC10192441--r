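Package: eyespeak
Title: Eye-Gesture Communication Decoding for Motor Neuron Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for decoding an eye-gesture communication language for
    patients with motor neuron disease (ALS/PLS) who retain only eye movement.
    Computes the eye aspect ratio (EAR) from 6-point eye landmarks, separates
    intentional language blinks from natural blinks by closed-run length,
    segments the pupil from eye-region images by masking, dilation, fixed
    thresholding and largest-contour extraction to classify gaze direction
    (left/right/up), and decodes fixed-length three-state gesture sequences
    into a 64-phrase dictionary. Includes a synthetic frame/landmark generator
    with exact ground truth, a bounded drop-oldest frame queue for streaming
    backpressure, and an analytic communication-speed model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
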