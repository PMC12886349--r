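---
title: "Normative qEEG deviance modelling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative qEEG deviance modelling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qeegnorm)
```

This vignette is the package's own account of the science it implements:
the models, the assumptions they rest on, the tunable parameters and their
defaults, what the synthetic-data generators do and do not emulate, and the
design choices made where the design was genuinely open.

## The modelling problem

Individual-level assessment of EEG abnormality in small, heterogeneous
patient cohorts is the core problem. Instead of comparing group means, the
package learns a *normative* low-dimensional space of qEEG features from a
typically developing reference cohort and scores each subject — reference
or patient — by a robust Mahalanobis distance from the normative center.
Clinical severity, measured on ordinal scales, is reduced to two principal
axes by a rank-based PCA, and the two sides are linked by rank correlations
with permutation inference.

## Spectral features

Eleven frequency bins span 1–44.8 Hz: delta is fixed at 1–4 Hz and ten bins
are logarithmically spaced above it, `edge(k+1)/edge(k) = (44.8/4)^(1/10)`.
Edges are held at full precision; only the display rounds to one decimal
(5.1, 6.5, 8.3, … Hz). Bins group into five canonical bands (δ: bin 1,
θ: 2–4, α: 5–6, β: 7–8, β-γ: 9–11). The canonical-band frequency ranges are
defined as unions of bins, so band boundaries are exactly bin edges — where
rounding could make a band edge ambiguous by one display step, the bins are
authoritative.

Power spectra use Welch's method with a Hamming window, segment and FFT
length `10*fs` (0.1 Hz resolution), 50% overlap rounded down, per-segment
mean removal, and a density normalisation under which the PSD integral
approximates the signal variance (checked to 5% in the tests). Band
integrals are cumulative-trapezoid evaluations at the exact (unrounded) bin
edges. Absolute power is `10*log10` of the band integral, i.e. dB relative
to one squared signal unit — the convention adopted since only "a dB scale"
is conventional in the field. Relative power divides by the total integral
over 1–45 Hz; because the bins end at 44.8 Hz the eleven shares sum to
slightly under 100% (by the 44.8–45 Hz sliver, negligible for 1/f-like
spectra).

## Long-range temporal correlations

Each band's amplitude envelope is the magnitude of the analytic signal of
the zero-phase band-passed series. Filters are Hamming-window FIRs with a
transition width of 25% of the lower band edge; one filter length is
trimmed from each side of the envelope to suppress transients. The DFA
exponent is the slope of log10 mean fluctuation versus log10 window size on
the cumulatively summed, mean-centered envelope, with least-squares linear
detrending per window. Defaults — fit range 2–20 s, 10 log-spaced window
sizes, 50% window overlap, linear detrending — are exposed in
`dfa_config()`; the literature this estimator follows does not fix a single
numeric fit range, so it is a configurable default rather than a constant.
Estimates are unreliable below about 100 s of signal, so such inputs warn;
below 20 s they error.

## Synthetic data: what it emulates, and what it does not

`gen_parcel_timeseries()` builds parcel signals as a 1/f^slope background
(band-limited to 1–45 Hz) plus one component per canonical band: a
constant-amplitude carrier (the cosine of the instantaneous phase of
band-passed white noise) multiplied by a positive envelope derived from
fractional Gaussian noise (FGN) whose Hurst parameter equals the target DFA
exponent. FGN is synthesised exactly by Davies–Harte circulant embedding,
giving an analytic oracle for the LRTC estimator. Two numerical choices
matter here:

* the envelope is log-normal, `exp(0.8 * FGN)`, rather than a shifted and
  clipped FGN — exponentiation guarantees positivity without the clipping
  distortion, preserves the long-memory exponent, and gives modulation deep
  enough that the planted exponent (not the carrier's own amplitude noise)
  dominates the measured envelope;
* the log-envelope is low-passed to 30% of the band width so that
  modulation sidebands stay inside the band. The cut-off sits far above the
  0.05–0.5 Hz fluctuations probed by the 2–20 s DFA fit range, so the
  planted scaling is unaffected while planted band powers are recovered to
  within ±0.05.

Component variances are chosen so the *measured* relative band powers match
their targets after accounting for the analytic share of the background
falling inside each band. The generator does not emulate scalp
acquisition, electrode montages, artifacts, preprocessing, or source
reconstruction: passing tests demonstrate correctness of the estimators and
of the downstream statistics on signals with known truth, not robustness to
real-world recording pathology.

Cohort features are drawn as `loadings · latent + age-slope · (age − mean
age) + noise`. The reference-like default (`tdc_cohort_spec()`) uses five
latent components, each supported on one canonical band across the seven
networks — mirroring the frequency-specific organisation of normative
pediatric qEEG — with decreasing variances chosen so five components retain
over 70% of the variance, a mild negative age slope on low-frequency
features and a mild positive one on alpha, and ages uniform on 4.3–18.2
years, the reference range of the study population this package models.
Ordinal clinical cohorts come from a Gaussian copula: a latent multivariate
normal with a target correlation matrix, discretised at per-scale
thresholds; this reproduces a target Spearman structure with ordinal
marginals, matching the rank-based analyses downstream. The patient
generator exposes deviation direction and magnitude as free parameters —
the amplitude distribution of real patient deviations is unknown, so it is
deliberately not fixed.

## Aggregation

Parcel × bin biomarkers collapse to 35 features (5 bands × 7 networks):
power sums across bins (dB values are converted to linear power first —
decibels do not add), DFA exponents take bin medians; within each
(network, hemisphere) cell the median across parcels is taken, and the left
and right hemisphere medians are then averaged. The mean-of-medians order
(rather than a pooled-parcel median) follows the aggregation description's
sentence order: medians per hemisphere first, then a hemisphere average.
The packaged 100-parcel map is a synthetic, balanced stand-in (7–8 parcels
per network per hemisphere); an atlas-derived table can be supplied as CSV.

## The normative space

Scaling is median/IQR, fitted on reference rows only and frozen — patient
rows are always expressed on the reference scale, and deleting patients
changes nothing (tested as a leakage property). The sparse PCA is a
sequential soft-thresholded power iteration with projection deflation: for
each component the loading update is `v <- soft(X'u, t)`, normalised, with
`t = (sparsity/20) * max|X'u|`. The exact penalised formulation behind a
single "sparsity parameter" is not standardised across implementations, so
this solver's scale was calibrated once so that the default `sparsity =
1.5` yields roughly 30–60% exact zero loadings on reference-like synthetic
cohorts; the parameter is exposed, `sparsity = 0` recovers classical PCA
(verified by cosine similarity > 0.99 per component), and planted disjoint
supports are recovered at higher sparsity. Because sparse loadings are not
exactly orthogonal, explained variance uses the adjusted-variance
convention — QR orthogonalisation of the score matrix — and components are
reordered by it. Signs are fixed so each component's largest-magnitude
loading is positive. The solver is deterministic (SVD initialisation,
tolerance 1e-8, at most 2000 iterations), so no seed is needed.

Projection applies the frozen scaler and the loading matrix with no
additional mean shift: scaled features have median zero by construction, so
a subject at the reference feature-space median scores exactly zero. Any
residual offset between the score-space mean and origin is absorbed by the
robust centers fitted downstream, and Mahalanobis distances are invariant
to it.

## Robust deviance

Centers and covariances in each component-pair plane come from the Minimum
Covariance Determinant with support `floor((n+3)/2)` — the `(n+3)/(2n)`
fraction, which for two dimensions coincides with the default of the
`MASS` implementation — and consistency-corrected scatter. The estimator's
subsampling is seeded locally, and the seed is recorded in the fit.
Distances are reported as the square root of the quadratic form: the
squared form is sometimes displayed in the literature, but distance
semantics require the root, and every downstream statistic is rank-based,
so the monotone choice is inconsequential. Reference subjects are scored by
leave-one-out jackknife (refit on the remaining n−1, score the held-out
point), which removes the optimism of scoring a subject against a reference
that contains it. Age-matched centers use reference subjects within ±12
months; if fewer than `min_n = 10` fall in the window the call errors with
the count rather than widening the window, because silent widening would
change the estimand. Raw (untransformed) distances feed the statistics.

## Clinical severity

The abnormality rubric has four categories — focal transient spectral
alterations (weight 2), focal-global epileptiform discharges (3),
focal-global diffuse beta (4), and global abnormalities: slow posterior
dominant rhythm, disrupted anterior-posterior gradient, or burst
suppression (5). A normal recording ranks 1; otherwise the rank is the sum
of the distinct category weights. Sub-labels (e.g. `slow_pdr`,
`burst_suppression`) alias into their category, and distinctness is counted
at the category level. For a minority of patients in the bundled cohort the
free-text clinical descriptions do not arithmetically reproduce the
published rank under these weights; the packaged table records the
published rank as authoritative and flags which rows the rubric reproduces
exactly.

`clinical_pca()` rank-transforms each scale (average ranks for ties — the
standard convention), computes the Spearman correlation matrix, and
eigendecomposes it; explained variance is eigenvalue over the number of
scales, and patient scores are z-scored ranks projected on the
eigenvectors. Two conventions are worth stating. First, signs: eigenvectors
are anchored so motor severity (GMFCS) loads positively on the first
component — "higher = more severe" — and the EEG severity rank negatively
on the second, matching the interpretation of the axes. Second, the
adequacy diagnostics: the overall KMO score and Bartlett's sphericity
statistic are computed from the *Pearson* correlation matrix of the raw
scores rather than the Spearman matrix of ranks. On the bundled cohort this
convention reproduces the published diagnostics exactly (KMO 0.83,
χ² 62.35), whereas the rank-based matrix does not (0.76, 83.3); the
eigendecomposition itself remains rank-based. The variance-standardized
clinical distance scales each retained axis by the inverse eigenvalue,
`sqrt(Σ score²/λ)`, preventing under-weighting of the lower-variance axis.

## Statistics

Paired state contrasts use the Wilcoxon signed-rank test with zero
differences dropped; for up to 14 nonzero differences the two-sided p-value
is exact by enumerating all sign assignments (valid under ties, because the
observed average ranks are used as-is), and the normal approximation with
tie correction otherwise. The effect size is `r = |Z|/sqrt(n)` with the
normal-approximation Z — this definition is convention-dependent across the
literature, which is why it is reported but not treated as a comparable
constant. The Shapiro–Wilk p-value on the differences is reported alongside
as the normality check motivating the non-parametric test.

Spearman correlations carry a two-tailed permutation p-value — `y` is
permuted, which under exchangeability is equivalent to permuting `x` — with
the add-one estimator `(1 + #{|ρ_perm| ≥ |ρ_obs|})/(1 + n_perm)`, so p is
never exactly zero, and an unstratified paired-bootstrap 95% percentile
interval; degenerate bootstrap resamples (a constant vector) are dropped
from the percentile computation. Benjamini–Hochberg FDR is applied within
each block of 10 component-pair tests, never across biomarker blocks.
Defaults are 15,000 permutations and 15,000 bootstraps.

## Problem sizes and determinism

The test suite and the examples run at the study's natural scales — 96
reference subjects, 15 patients, 35 features, 5 components — with
resampling reduced to 200–1,500 draws and Monte-Carlo calibrations at a few
hundred replicates; these sizes were chosen so the whole suite documents
the pipeline's behaviour in well under a minute while leaving every
statistical check comfortably powered. Every generator and every stochastic
estimator takes an explicit seed, saves and restores the caller's RNG
state, and is bitwise reproducible; `run_pipeline()` derives per-stage
streams from one master seed and records them in its manifest.

## Known limitations

* The raw-EEG side (preprocessing, source reconstruction, atlas
  construction) is out of scope; parcel time series are consumed as given.
* The sparse-PCA solver is one member of a family of penalised formulations;
  with a different formulation the same "sparsity 1.5" would yield a
  different zero fraction. The calibration documented above, not asserted
  equivalence, is the contract.
* Jackknifed squared distances are only approximately χ²(2): the MCD's
  finite-sample support inflates tails slightly, which the tests
  acknowledge with a loose Kolmogorov–Smirnov bound.
* Age-matched deviances require local reference density; cohorts whose age
  windows are under-populated fail loudly by design.
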