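Package: scgrisk
Title: Coronary Artery Disease Risk Scoring from Rest Seismocardiography and
    Gyrocardiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for scoring coronary artery disease (CAD)
    risk from resting seismocardiography (SCG, sternal accelerometry) and
    gyrocardiography (GCG, sternal gyroscopy) recorded alongside a reference
    ECG. Implements zero-phase Butterworth baseline-wander removal,
    normalization and Chebyshev-I decimation; Pan-Tompkins QRS detection and
    ECG-Q anchored cardiac-cycle segmentation with linear interpolation to a
    fixed cycle length; synchrosqueezing wavelet time-frequency features
    reduced to per-cycle intensity images; per-channel one-dimensional
    convolutional neural network classifiers trained with Adam; and
    leave-one-subject-out evaluation with ensemble fusion across channels,
    reporting AUC with DeLong confidence intervals, confusion-matrix metrics
    with Wilson intervals, and the discrimination slope. Ships a synthetic
    cohort generator with controllable spectral class separation so the full
    experiment runs without access to clinical data, plus CSV/EDF/WFDB
    readers and writers for multi-channel recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pROC,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
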