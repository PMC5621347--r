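Package: tremorscore
Title: Tremor Severity Scoring from Wearable Inertial Sensor Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for automatic scoring of Parkinsonian resting-tremor
    severity (UPDRS 0-4) from wrist/finger-worn tri-axial accelerometer and
    gyroscope recordings. Includes signal preprocessing (Butterworth
    band-pass, integration to displacement and angle, middle-segment
    extraction), extraction of 19 temporal and spectral features per signal
    with adaptive tremor-frequency bands, pairwise-correlation and PCA
    feature selection, leave-one-out evaluation of five classifier families,
    an ordinal-error evaluation framework (error CDF, NAuC, per-class recall
    and precision with Wald intervals), and a severity-graded synthetic
    tremor simulator for end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    MASS,
    rpart,
    randomForest,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
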