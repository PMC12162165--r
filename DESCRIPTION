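Package: specklesense
Title: Laser Speckle Vibrometry Simulation, Tracking and Boosted-Tree
    Classification of Stimulus-Evoked Surface Vibrations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for remote vibration sensing with secondary laser
    speckle patterns: a Fourier-optics simulator that renders speckle
    videos whose subpixel translation encodes class-specific surface-tilt
    signals, a normalized cross-correlation tracker with parabolic
    subpixel refinement, fixed-schema time-series feature extraction over
    40-frame chunks, a from-scratch second-order gradient-boosted tree
    classifier with softmax multi-class loss, a tree-structured
    Parzen-estimator style hyperparameter sampler, confusion-matrix
    metrics, and an experiment orchestrator with leakage-safe per-subject
    video-tag splits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    xgboost,
    caret,
    optparse
Config/testthat/edition: 3
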