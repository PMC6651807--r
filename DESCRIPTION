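Package: fdbhrt
Title: Heart-Rate-Gated Threshold Fall Detection for Wearable Sensor Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic streaming implementation of a hybrid fall
    detection algorithm for body-worn sensors that gates accelerometer
    free-fall detection on a sustained abnormal heart rate (FDB-HRT).
    Includes seeded generators for labelled fall and activities-of-daily-
    living traces, treadmill stand/run/fall scenarios, paired device-versus-
    benchmark heart-rate readings and jittered GPS fixes; evaluation
    statistics (confusion-matrix metrics, mean absolute error, histogram
    binning, per-coordinate geolocation error); and emergency-dispatch
    arithmetic (UAV-versus-ambulance time savings, wearable battery-life
    estimation) together with alert-message composition and parsing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    withr,
    geosphere,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
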