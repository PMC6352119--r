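Package: ppght
Title: Hypertension Risk Stratification from Photoplethysmogram Morphology
Version: 0.1.0
Authors@R:
    person("PPG", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for screening hypertension from short
    single-channel fingertip photoplethysmogram (PPG) records. Provides a
    synthetic cohort generator with class-dependent reflected-wave morphology,
    skewness-based signal quality selection, zero-phase Chebyshev type-II
    bandpass filtering and derivative waveforms (VPG/APG), fiducial point
    delineation (O/S/N/D, w/x/y/z, a/b/c/d/e), a 125-feature morphological
    catalogue, six filter-type feature ranking methods (Spearman, ReliefF,
    information gain, chi-square, mRMR, Gini), and stratified 10-fold
    cross-validated classification (LDA, logistic regression, cubic SVM,
    weighted KNN) reporting sensitivity, positive predictivity and F1 for
    pairwise blood-pressure group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
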