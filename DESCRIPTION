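Package: multifall
Title: Multiphase Fall Detection from Wearable Accelerometer Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects falls in continuous 100 Hz triaxial accelerometer
    recordings from a lower-back worn sensor. Implements peak-anchored
    sliding-window segmentation of the acceleration norm into candidate
    fall windows, feature extraction based on a multiphase fall model
    (pre-peak descent, impact, post-impact rest or recovery), classifier
    training with subject-stratified cross-validation under class
    imbalance, a multi-threshold comparator detector, and an evaluation
    suite centred on false alarms per monitored hour. Includes a
    synthetic signal generator emulating activities of daily living and
    multiphase falls for development and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    e1071,
    randomForest,
    class,
    signal
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
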