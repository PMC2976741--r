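Package: mapcast
Title: Forecasting Impending Hypotension from ICU Hemodynamic Trend Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for predicting hypotensive episodes in
    intensive-care patients from minute-by-minute hemodynamic trend records
    (heart rate and systolic, diastolic and mean arterial blood pressure).
    Provides a plain-text record format, a seeded synthetic-cohort generator
    with controllable pre-episode signatures, sliding-window example
    compilation with hypotensive-episode labeling, a 102-dimensional feature
    extractor (statistical, zero-lag cross-correlation, discrete Meyer
    wavelet relative-energy and clinical features), z-score plus PCA
    dimensionality reduction, feed-forward neural-network classification and
    median-MAP regression with early stopping, record-level cross-validation
    with majority-class sub-sampling, and a minute-by-minute continuous
    monitoring mode.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
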