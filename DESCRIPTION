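Package: ecgwellness
Title: One-Day-Forward Wellness Prediction from Short Single-Lead ECG
    Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Feature engineering and predictive modelling for daily wellness
    forecasting in older adults from short (20-25 s) single-lead ECG records.
    Builds a 184-dimensional feature vector per 5-second segment from four
    signal-analysis families: time- and frequency-domain statistics,
    three-level wavelet-packet sub-band energies, ensemble empirical mode
    decomposition (EEMD) with per-IMF time-domain statistics, and refined
    composite multiscale sample entropy (RCMSE). Includes a seeded synthetic
    ECG cohort generator, sliding-window segmentation, min-max feature
    normalization, rank-based (Fisher-Yates) conversion of ordinal self-rated
    health scores to binary labels, random-forest and PSO-tuned RBF-SVM
    classifiers, and the standard confusion-matrix metrics with hold-out and
    repeated-split cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    e1071,
    randomForest,
    signal,
    stats,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
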