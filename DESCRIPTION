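Package: qeegnorm
Title: Normative Modelling of Quantitative EEG Biomarkers with Robust
    Mahalanobis Deviance and Ordinal Clinical Severity Axes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds normative reference spaces for quantitative EEG (qEEG)
    biomarkers and quantifies individual deviations from them. Implements
    log-spaced band schemes with Welch band power estimation, long-range
    temporal correlations via detrended fluctuation analysis of Hilbert
    amplitude envelopes, aggregation of parcel-level biomarkers into
    band-by-network feature matrices, robust median/IQR scaling with sparse
    principal component analysis fitted on a reference cohort, Minimum
    Covariance Determinant based Mahalanobis distances with global and
    age-matched centers, an additive ordinal severity rubric for visually
    scored EEG abnormalities, rank-based clinical PCA with adequacy
    diagnostics, and permutation/bootstrap Spearman statistics linking EEG
    deviance to clinical severity axes. A synthetic-data module generates
    parcel time series and cohorts with known ground truth so the whole
    pipeline is testable without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    signal,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
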