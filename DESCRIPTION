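Package: rflhar
Title: Hybrid Random-Forest/LSTM Transfer Features for Wearable-Sensor
    Exercise Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies physiotherapy exercises from 9-channel inertial and
    magnetic sensor streams (tri-axial accelerometer, gyroscope and
    magnetometer at 25 Hz) using hybrid transfer features: per-class
    probabilities averaged over the trees of a random forest concatenated
    with the final hidden state of a single-layer LSTM. Includes a synthetic
    IMU data generator with controllable class separability, leakage-aware
    out-of-fold feature extraction, stratified splitting, four downstream
    classifiers with reference hyperparameters, and a classification-report /
    k-fold evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    rpart,
    nnet,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
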