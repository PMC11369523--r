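Package: dtball
Title: Dual-Task Ball-Balancing Assessment Analytics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analytics for a tablet-based dual-task ball-balancing
    assessment of cognitive function. Reads inertial measurement unit (IMU)
    trial recordings, conditions the signals (trimming, duration gating,
    uniform resampling, zero-phase Butterworth band-pass filtering,
    calibration), derives the on-screen virtual-ball trajectory from tablet
    tilt through a Newtonian kinematic model, extracts postural-sway style
    ball-position and inertial-sensor feature suites under single- and
    dual-task conditions, computes dual-task cost, and runs the downstream
    statistical analyses (dichotomization of cognitive outcome measures,
    rank tests, age-adjusted ANCOVA, functional-impairment independence
    checks) and cross-validated logistic-regression classification with
    sequential forward feature selection. A closed-loop human-controller
    simulator generates complete synthetic cohorts so every stage is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    signal,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
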