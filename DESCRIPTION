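Package: gripsense
Title: Grip Strength Estimation from Smartphone Touch and Inertial Sensing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates maximal hand grip strength (kg) from the way a person
    performs short touchscreen tasks (tapping, flicking, spiral dragging) on a
    smartphone, using behavioral touch features and windowed statistics of
    60 Hz inertial sensor streams. Implements the full pipeline: session-log
    data model and JSON-Lines input/output, task geometry including an
    Archimedean reference spiral and left-hand mirroring, sensor preprocessing
    (gap interpolation, zero-phase 20 Hz low-pass filtering, event-anchored
    windows), feature extraction, four regression back ends (random forest,
    RBF support vector regression, gradient boosting, distance-weighted k-NN)
    behind a single fitting interface, and three validation protocols
    (5-fold cross-validation, leave-one-user-out, few-day personal
    calibration) with MAE/MAPE/R-squared reporting. A synthetic cohort
    generator with a latent grip-fatigue model makes the whole pipeline
    testable without human data. Raw NASA-TLX workload scoring is included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    signal,
    e1071,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
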