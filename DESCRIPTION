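Package: rehabsense
Title: Wearable Accelerometer and BLE Beacon Analytics for Subacute
    Rehabilitation Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of wrist-worn triaxial accelerometer streams
    and Bluetooth low-energy (BLE) beacon observations collected from
    subacute-rehabilitation patients. Implements signal-magnitude band-pass
    processing with mean-absolute-deviation (MAD) activity quantification,
    hierarchical activity recognition (walking/stationary, active/idle,
    stand/sit/lay), nearest-beacon indoor localization with received signal
    strength (RSSI) smoothing, baseline-day inclusion rules, normalized
    time/energy feature engineering, and the cohort statistics layer
    (Kruskal-Wallis, chi-square, Cohen's d, Spearman correlations,
    cross-validated random-forest outcome models). Ships a protocol-faithful
    synthetic cohort generator (wear protocol, posture-dependent gravity,
    walking oscillation, log-distance path-loss RSSI) so every stage is
    testable without access to clinical sensor data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    randomForest,
    e1071,
    pROC,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'signal-processing.R'
    'activity-recognition.R'
    'indoor-localization.R'
    'feature-engine.R'
    'cohort-stats.R'
    'published-summaries.R'
    'io.R'
    'pipeline.R'
    'rehabsense-package.R'
    'synthetic-cohort.R'
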