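Package: restmotion
Title: Resting-Hand Tremor Quantification and Classification from Two-IMU Recordings
Version: 0.1.0
Authors@R:
    person("restmotion", "developers", email = "restmotion@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for classifying Parkinson's-disease-like
    resting tremor from paired inertial measurement units (hand and forearm),
    each carrying a triaxial accelerometer, gyroscope and magnetometer sampled
    at 50 Hz. Provides a seeded synthetic-cohort generator, zero-phase
    Butterworth band-pass preprocessing with resultant and mean-detrend steps,
    18 time/frequency/entropy features per sensor (108 per subject), ReliefF
    feature ranking with percentage subsets, four classifiers (KNN, polynomial
    SVM, random forest, Gaussian naive Bayes), and confusion-matrix evaluation
    with stratified train/test splits and tenfold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
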