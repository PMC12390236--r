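Package: pdsense
Title: Sensor-Based Severity Estimation for Parkinson's Disease Motor Symptoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline that turns tri-axial accelerometer and
    gyroscope recordings of standardized motor exercises (rest, postural,
    pronation-supination) into continuous severity estimates for the four
    cardinal Parkinson's disease motor symptoms (tremor, bradykinesia,
    stiffness, dyskinesia, each on a 0-4 scale) and for an overall
    treatment-response state on a -4..+4 scale. Provides a synthetic cohort
    generator with severity-encoded signal components, Butterworth-based
    signal conditioning, a bank of time-domain, spectral, short-time Fourier,
    windowed and wavelet features, two-step correlation/importance-guided
    feature selection, random-forest, gradient-boosting and support-vector
    regression with 10-fold and leave-one-patient-out cross-validation, and
    class-balanced error metrics for imbalanced ordinal targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    ranger,
    xgboost,
    e1071,
    jsonlite,
    yaml,
    ggplot2,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
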