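Package: gaitseg
Title: Stride Segmentation and Gait-Event Detection from Foot-Worn IMU Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage gait analysis toolkit for six-axis inertial
    recordings from foot-worn sensors. Long recordings are segmented into
    regions of motion, each candidate region is summarised by a normalized
    signal image plus a dynamic-time-warping/correlation score vector, and a
    small convolutional network ('stepperNet') separates walking strides from
    non-stride motion. Within accepted strides the four gait events heel off,
    toe off, heel strike and flat foot are located by signal rules. The
    package also includes a multi-annotator toolkit that condenses gait-event
    labels from several human labelers via Needleman-Wunsch alignment and
    quantifies inter-labeler disagreement as a percentile limit of agreement,
    together with a parametric synthetic-data generator so the whole pipeline
    can be exercised without access to recorded gait data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
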