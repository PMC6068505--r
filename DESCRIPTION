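Package: gaze3d
Title: Free-Space 3D Point-of-Regard Estimation from Binocular Eye Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the three-dimensional Point-of-Regard (the point in
    space a person is looking at) from near-infrared stereo images of both
    eyes. Implements adaptive gradient pupil-edge extraction with two-step
    RANSAC/least-squares ellipse fitting, multi-scale Harris inner-eye-corner
    detection, epipolar feature matching and 3D pupil-circle reconstruction,
    a shrinking grid search that calibrates per-eye line-of-sight convergence
    points against a four-cross calibration board, an inner-eye-corner-vector
    coordinate alignment, and a quadratic pupil-size model that predicts the
    convergence points at run time. The Point-of-Regard is the midpoint of
    the nearest points of the two sightlines. A fully ground-truthed
    synthetic binocular rig (feature tracks and rendered eye images) makes
    every stage testable without recorded human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
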