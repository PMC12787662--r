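Package: tricadence
Title: Movement Cadence Detection and Longitudinal Modelling from a
    Single Trunk-Worn IMU
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for measuring and modelling movement cadence (swimming
    strokes, cycling pedal strokes and running strides per minute) from a
    single trunk-mounted inertial measurement unit worn during triathlon
    racing.  Provides discipline-specific peak-counting detectors
    (zero-phase Butterworth filtering, prominence-thresholded extrema,
    refractory-interval thinning and cross-sensor confirmation for
    cycling), race-level inclusion/averaging/imputation rules, a
    penalized thin-plate-spline mixed model of cadence over a season
    fitted by restricted maximum likelihood with per-athlete random
    intercepts and slopes, linear-versus-smooth model comparison via
    AIC/BIC/likelihood-ratio tests, prediction curves with pointwise 95%
    confidence intervals, weekly percentage-change summaries, and a
    synthetic-data module that generates IMU recordings with known event
    times and season-long cadence datasets with known parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    mgcv,
    nortest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
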