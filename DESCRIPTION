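Package: liveplay
Title: Automated Detection of Live-Play Periods in Basketball from
    Accelerometry-Derived Exercise Intensity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects on-court, clock-running (live play) periods in
    basketball matches from wearable accelerometer data. Raw triaxial
    acceleration is band-pass filtered, converted to per-second relative
    exercise intensity (percent of oxygen uptake reserve) via average net
    force and per-player calibration, smoothed with a moving-average
    sample window and thresholded, with gap-filling and team-level
    substitution rules, then segmented into live-play periods. Includes
    grid-search plus quadratic response-surface optimisation of the
    window and threshold parameters, a criterion-validity statistical
    battery (per-second confusion matrix, Spearman's rho, absolute-
    agreement intraclass correlation with confidence intervals, median
    bias with 5th/95th percentiles), and a synthetic match simulator for
    testing without access to match recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
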