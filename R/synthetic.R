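# Synthetic-data generators: parcel time series with planted spectral and
# temporal structure, cohort feature matrices with planted covariance and age
# trends, paired eyes-open/eyes-closed states, and ordinal clinical cohorts.
# Every generator is deterministic under its seed and returns the planted
# ground truth alongside the data.

#' Specification for synthetic parcel time series
#'
#' Describes band-limited oscillations riding on a 1/f background. Each
#' canonical band contributes a band-pass carrier multiplied by a positive
#' (log-normal) envelope derived from fractional Gaussian noise whose Hurst
#' parameter equals the target DFA exponent, so planted long-range temporal
#' correlations have an analytic oracle.
#'
#' @param n_parcels number of cortical parcels
#' @param fs sampling rate (Hz); must exceed twice the highest band edge
#' @param duration seconds per parcel; below 100 s planted DFA targets are
#'   flagged as unreliable
#' @param rel_power named fractions of total 1-45 Hz power per canonical
#'   band (nonnegative, summing to <= 1; remainder goes to the background)
#' @param dfa_exponents named target DFA exponents per canonical band, in
#'   `[0.5, 1)`
#' @param background_slope exponent of the 1/f^slope background PSD
#' @param seed integer RNG seed
#' @return object of class `signal_spec`
#' @export
signal_spec <- function(n_parcels = 100,
                        fs = 250,
                        duration = 180,
                        rel_power = c(
                          delta = 0.30, theta = 0.20, alpha = 0.20,
                          beta = 0.10, beta_gamma = 0.05
                        ),
                        dfa_exponents = c(
                          delta = 0.60, theta = 0.65, alpha = 0.70,
                          beta = 0.65, beta_gamma = 0.60
                        ),
                        background_slope = 1,
                        seed = 1L) {
  sch <- band_scheme()
  bands <- canonical_bands(sch)
  rel_power <- rel_power[bands]
  dfa_exponents <- dfa_exponents[bands]
  if (anyNA(rel_power) || any(rel_power < 0) || sum(rel_power) > 1 + 1e-12) {
    stop("'rel_power' must name all five canonical bands, be nonnegative and sum to <= 1")
  }
  if (anyNA(dfa_exponents) || any(dfa_exponents < 0.5) || any(dfa_exponents >= 1)) {
    stop("'dfa_exponents' must name all five canonical bands with values in [0.5, 1)")
  }
  if (fs <= 2 * max(sch$edges)) {
    stop(sprintf("fs = %g Hz must exceed twice the highest band edge (%g Hz)", fs, max(sch$edges)))
  }
  if (n_parcels < 1 || duration <= 0) stop("'n_parcels' and 'duration' must be positive")
  structure(
    list(
      n_parcels = as.integer(n_parcels), fs = fs, duration = duration,
      rel_power = rel_power, dfa_exponents = dfa_exponents,
      background_slope = background_slope, seed = as.integer(seed),
      scheme = sch
    ),
    class = "signal_spec"
  )
}

# 1/f^slope noise band-limited to `range`, unit variance
shaped_background <- function(n, fs, slope, range = c(1, 45)) {
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f) # two-sided frequency axis
  amp <- ifelse(f >= range[1] & f <= range[2], f^(-slope / 2), 0)
  x <- Re(stats::fft(stats::fft(stats::rnorm(n)) * amp, inverse = TRUE)) / n
  x / stats::sd(x)
}

# zero out spectral content outside `range` so all of a component's variance
# counts toward the 1-45 Hz power budget
fft_bandlimit <- function(x, fs, range) {
  n <- length(x)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  keep <- f >= range[1] & f <= range[2]
  Re(stats::fft(stats::fft(x) * keep, inverse = TRUE)) / n
}

# constant-amplitude band-limited carrier: the cosine of the instantaneous
# phase of band-passed white noise, so that the planted envelope is the
# dominant amplitude modulation
band_carrier <- function(n, fs, band) {
  pad <- as.integer(2 * ceiling(3.3 * fs / (0.25 * band[1]))) # two filter lengths
  z <- band_filter(stats::rnorm(n + 2L * pad), fs, band)
  ph <- Arg(analytic_signal(z))
  cos(ph)[(pad + 1L):(pad + n)]
}

#' Generate parcel time series with planted structure
#'
#' Each parcel is an independent realisation of the same specification: a
#' band-limited 1/f background plus, per canonical band, a constant-amplitude
#' band-pass carrier multiplied by a positive envelope built from fractional
#' Gaussian noise with Hurst parameter equal to the band's target DFA
#' exponent. Component variances are chosen so that the measured relative
#' power of each canonical band matches its target after accounting for the
#' analytic share of the background that falls inside the band.
#'
#' @param spec a [signal_spec()]
#' @return object of class `parcel_sim`: list with `signals` (n_parcels x
#'   samples matrix), `fs`, and `ground_truth` (planted relative powers, DFA
#'   exponents, per-band component variances, warnings)
#' @export
gen_parcel_timeseries <- function(spec) {
  stopifnot(inherits(spec, "signal_spec"))
  sch <- spec$scheme
  n <- as.integer(round(spec$fs * spec$duration))
  warnings <- character()
  if (spec$duration < 100 && any(spec$dfa_exponents > 0.5)) {
    warnings <- c(warnings, sprintf(
      "duration %.1f s is below the ~100 s needed for reliable DFA; planted exponents are unreliable",
      spec$duration
    ))
    warning(warnings[length(warnings)])
  }
  # analytic share of the 1/f background falling in each canonical band
  s <- spec$background_slope
  bg_int <- function(lo, hi) {
    if (abs(s - 1) < 1e-9) log(hi / lo) else (hi^(1 - s) - lo^(1 - s)) / (1 - s)
  }
  tot <- bg_int(sch$range[1], sch$range[2])
  bg_share <- vapply(sch$band_edges, function(e) bg_int(e[1], e[2]) / tot, numeric(1))
  bg_total <- 1 - sum(spec$rel_power)
  comp_var <- spec$rel_power - bg_total * bg_share
  if (any(comp_var < 0)) {
    warnings <- c(warnings, "some band targets are below the background's own band share; clamped to zero")
    warning(warnings[length(warnings)])
    comp_var <- pmax(comp_var, 0)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  signals <- matrix(0, spec$n_parcels, n)
  for (p in seq_len(spec$n_parcels)) {
    x <- sqrt(bg_total) * shaped_background(n, spec$fs, s, sch$range)
    for (b in names(sch$band_edges)) {
      if (comp_var[[b]] <= 0) next
      carrier <- band_carrier(n, spec$fs, sch$band_edges[[b]])
      # log-normal envelope: strictly positive, deep modulation, and the
      # long-memory exponent of the FGN log-envelope carries through to the
      # measured amplitude envelope
      # log-envelope low-passed to a fraction of the band width so the
      # modulation sidebands stay inside the band; the cut is far above the
      # 0.05-0.5 Hz scales probed by the DFA fit range, so the planted
      # long-memory exponent is preserved
      edges <- sch$band_edges[[b]]
      g <- fgn(n, spec$dfa_exponents[[b]])
      g <- fft_bandlimit(g, spec$fs, c(0, 0.3 * (edges[2] - edges[1])))
      env <- exp(0.8 * g / stats::sd(g))
      comp <- fft_bandlimit(carrier * env, spec$fs, sch$range)
      x <- x + sqrt(comp_var[[b]]) * comp / stats::sd(comp)
    }
    signals[p, ] <- x
  }
  structure(
    list(
      signals = signals, fs = spec$fs,
      ground_truth = list(
        rel_power = spec$rel_power,
        dfa_exponents = spec$dfa_exponents,
        component_variance = comp_var,
        background_fraction = bg_total,
        seed = spec$seed,
        warnings = warnings
      ),
      spec = spec
    ),
    class = "parcel_sim"
  )
}

# save/restore the global RNG state so seeded generators do not disturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Specification for a synthetic biomarker cohort
#'
#' Feature rows are drawn as `loadings %*% latent + age_slope * (age - mean
#' age) + noise`, with latent component scores independent Gaussians of the
#' given variances and ages uniform over the range.
#'
#' @param n_subjects cohort size
#' @param loadings features x components matrix (defaults to the band-block
#'   structure of [tdc_cohort_spec()])
#' @param comp_var positive variance per latent component
#' @param noise_var isotropic residual variance
#' @param age_range ages are sampled uniformly over this range (years)
#' @param age_slope per-feature change per year (scalar or length-n_features)
#' @param seed integer RNG seed
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(n_subjects, loadings, comp_var, noise_var = 0.15,
                        age_range = c(4.3, 18.2), age_slope = 0, seed = 1L) {
  loadings <- as.matrix(loadings)
  if (ncol(loadings) > nrow(loadings)) stop("more components than features")
  if (length(comp_var) != ncol(loadings)) stop("one variance per component required")
  if (any(comp_var <= 0)) stop("component variances must be positive (degenerate component)")
  if (noise_var < 0) stop("'noise_var' must be nonnegative")
  structure(
    list(
      n_subjects = as.integer(n_subjects), loadings = loadings,
      comp_var = as.numeric(comp_var), noise_var = noise_var,
      age_range = age_range,
      age_slope = rep_len(age_slope, nrow(loadings)),
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Reference-cohort specification mimicking typical development
#'
#' Five latent components, each supported on one canonical band across the
#' seven networks (the frequency-specific organisation seen in normative
#' pediatric qEEG), with decreasing variances and a mild age trend on the
#' low-frequency features. With the default variances the five components
#' account for over 70% of the total feature variance.
#'
#' @param n_subjects cohort size (default 96)
#' @param seed integer RNG seed
#' @param age_range ages sampled uniformly over this range (years)
#' @return a [cohort_spec()] with 35 features named `band_network`
#' @export
tdc_cohort_spec <- function(n_subjects = 96, seed = 1L, age_range = c(4.3, 18.2)) {
  bands <- canonical_bands()
  nets <- network_labels()
  feat <- as.vector(outer(bands, nets, paste, sep = "_"))
  L <- matrix(0, 35, 5, dimnames = list(feat, paste0("C", 1:5)))
  for (k in seq_along(bands)) {
    L[grep(paste0("^", bands[k], "_"), feat), k] <- 1 / sqrt(7)
  }
  slope <- ifelse(grepl("^delta_|^theta_", feat), -0.03,
    ifelse(grepl("^alpha_", feat), 0.02, 0)
  )
  cohort_spec(
    n_subjects = n_subjects, loadings = L,
    comp_var = c(8, 5, 4, 3, 2.5), noise_var = 0.15,
    age_range = age_range, age_slope = slope, seed = seed
  )
}

#' Generate a cohort feature matrix with known ground truth
#'
#' @param spec a [cohort_spec()]
#' @param cohort cohort label recorded in the metadata (default "TDC")
#' @param state recording state label (default "EOR")
#' @return data.frame with metadata columns (`subject`, `cohort`, `state`,
#'   `age_years`, `sex`) followed by the feature columns; planted latent
#'   scores and the spec are stored in the `ground_truth` attribute
#' @export
gen_cohort_features <- function(spec, cohort = "TDC", state = "EOR") {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  n <- spec$n_subjects
  p <- nrow(spec$loadings)
  k <- ncol(spec$loadings)
  z <- matrix(stats::rnorm(n * k), n, k) %*% diag(sqrt(spec$comp_var), k)
  age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  noise <- matrix(stats::rnorm(n * p, sd = sqrt(spec$noise_var)), n, p)
  X <- z %*% t(spec$loadings) + outer(age - mean(age), spec$age_slope) + noise
  feat <- rownames(spec$loadings)
  if (is.null(feat)) feat <- paste0("f", seq_len(p))
  colnames(X) <- feat
  out <- data.frame(
    subject = sprintf("S%03d", seq_len(n)),
    cohort = cohort, state = state,
    age_years = age,
    sex = sample(c("M", "F"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(X))
  attr(out, "ground_truth") <- list(latent = z, spec = spec)
  attr(out, "features") <- feat
  out
}

#' Feature column names of a cohort data frame
#' @param fm a feature data.frame from the generators or read from CSV
#' @return character vector of feature column names
#' @export
feature_cols <- function(fm) {
  f <- attr(fm, "features")
  if (!is.null(f)) {
    return(f)
  }
  meta <- c("subject", "cohort", "state", "age_years", "sex")
  setdiff(names(fm), meta)
}

#' Numeric feature matrix of a cohort data frame
#' @inheritParams feature_cols
#' @return numeric matrix (subjects x features) with subject rownames
#' @export
feature_values <- function(fm) {
  m <- as.matrix(fm[, feature_cols(fm), drop = FALSE])
  if ("subject" %in% names(fm)) rownames(m) <- fm$subject
  m
}

#' Generate a relative-power style cohort
#'
#' Produces a cohort whose five band values within each network are positive
#' and sum to exactly 100%, as relative power features do: band-level mean
#' shares are perturbed by a [tdc_cohort_spec()]-style latent structure,
#' clipped to a small positive floor and renormalised per network.
#'
#' @param n_subjects cohort size
#' @param seed integer RNG seed
#' @param state recording state label
#' @return feature data.frame as in [gen_cohort_features()]
#' @export
gen_relpower_cohort <- function(n_subjects = 96, seed = 1L, state = "EOR") {
  fm <- gen_cohort_features(tdc_cohort_spec(n_subjects, seed), state = state)
  X <- feature_values(fm)
  mu <- c(delta = 30, theta = 22, alpha = 25, beta = 15, beta_gamma = 8)
  band_of <- sub("_.*$", "", colnames(X))
  X <- sweep(2.5 * scale(X, scale = FALSE), 2, mu[band_of], "+")
  X <- pmax(X, 0.5)
  for (net in network_labels()) {
    idx <- grep(paste0("_", net, "$"), colnames(X))
    X[, idx] <- 100 * X[, idx] / rowSums(X[, idx])
  }
  fm[, colnames(X)] <- X
  fm
}

#' Paired eyes-open / eyes-closed relative-power states
#'
#' The eyes-closed rows equal the eyes-open rows with the alpha- and
#' theta-band relative-power features multiplied by the given boosts and each
#' network's five band values renormalised to sum to 100%, preserving
#' subject pairing. Eye closure characteristically boosts alpha (and
#' modulates theta), so this emulates the canonical physiological contrast.
#'
#' @param eor a relative-power feature data.frame (e.g.
#'   [gen_relpower_cohort()]); band values per network must be nonnegative
#' @param alpha_boost multiplicative boost (> 0) for alpha features
#' @param theta_boost multiplicative boost (> 0) for theta features
#' @return list with `eor` and `ecr` feature data.frames
#' @export
gen_state_pair <- function(eor, alpha_boost = 1.6, theta_boost = 1.2) {
  if (alpha_boost <= 0 || theta_boost <= 0) stop("boosts must be positive")
  X <- feature_values(eor)
  if (any(X < 0)) stop("relative-power features must be nonnegative")
  boost <- ifelse(grepl("^alpha_", colnames(X)), alpha_boost,
    ifelse(grepl("^theta_", colnames(X)), theta_boost, 1)
  )
  Y <- sweep(X, 2, boost, "*")
  for (net in network_labels()) {
    idx <- grep(paste0("_", net, "$"), colnames(Y))
    if (length(idx)) Y[, idx] <- 100 * Y[, idx] / rowSums(Y[, idx, drop = FALSE])
  }
  ecr <- eor
  ecr[, colnames(Y)] <- Y
  if ("state" %in% names(ecr)) ecr$state <- "ECR"
  list(eor = eor, ecr = ecr)
}

#' Age-match a synthetic patient cohort to a reference cohort
#'
#' Reassigns each patient an age drawn (with small uniform jitter) from the
#' reference ages whose surrounding age window already contains at least
#' `min_n` reference subjects, emulating the age-matched recruitment of a
#' patient cohort. The planted per-feature age-trend contribution is
#' adjusted exactly for the age change, so the generative model is
#' preserved.
#'
#' @param patients patient feature data.frame from [gen_cohort_features()]
#' @param reference reference feature data.frame with `age_years`
#' @param window age half-window (years) that must be well supported
#' @param min_n minimum reference subjects required within the window
#' @param jitter half-width of the uniform age jitter (years)
#' @param seed integer RNG seed
#' @return the patient data.frame with matched `age_years`
#' @export
match_ages_to_reference <- function(patients, reference, window = 1, min_n = 10,
                                    jitter = 0.2, seed = 1L) {
  ref_ages <- reference$age_years
  support <- vapply(ref_ages, function(a) {
    sum(abs(ref_ages - a) <= window - jitter)
  }, numeric(1))
  eligible <- ref_ages[support >= min_n]
  if (!length(eligible)) {
    stop(sprintf("no reference age has %d subjects within +/- %g years", min_n, window - jitter))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- nrow(patients)
  new_age <- sample(eligible, n, replace = TRUE) + stats::runif(n, -jitter, jitter)
  gt <- attr(patients, "ground_truth")
  if (!is.null(gt$spec$age_slope)) {
    fc <- feature_cols(patients)
    patients[, fc] <- as.matrix(patients[, fc]) +
      outer(new_age - patients$age_years, gt$spec$age_slope)
  }
  patients$age_years <- new_age
  patients
}

#' Specification for a synthetic ordinal clinical cohort
#'
#' Ordinal scales are generated through a Gaussian copula: a latent
#' multivariate normal with the given correlation matrix is discretised at
#' per-scale thresholds into ordinal levels, reproducing a target Spearman
#' structure with ordinal marginals.
#'
#' @param n_patients cohort size
#' @param latent_corr symmetric positive semidefinite correlation matrix
#'   (unit diagonal), one row per scale
#' @param scales named list; each element is a list with `levels` (ordinal
#'   values, increasing) and `thresholds` (latent cutpoints, length
#'   `length(levels) - 1`)
#' @param seed integer RNG seed
#' @return object of class `clinical_cohort_spec`
#' @export
clinical_cohort_spec <- function(n_patients = 15,
                                 latent_corr = default_clinical_corr(),
                                 scales = default_clinical_scales(),
                                 seed = 1L) {
  latent_corr <- as.matrix(latent_corr)
  p <- nrow(latent_corr)
  if (p != ncol(latent_corr) || max(abs(latent_corr - t(latent_corr))) > 1e-8) {
    stop("'latent_corr' must be a symmetric square matrix")
  }
  if (max(abs(diag(latent_corr) - 1)) > 1e-8) stop("'latent_corr' must have unit diagonal")
  ev <- eigen(latent_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(sprintf("'latent_corr' is not positive semidefinite (smallest eigenvalue %.4g)", min(ev)))
  }
  if (length(scales) != p) stop("one scale definition per correlation row required")
  structure(
    list(
      n_patients = as.integer(n_patients), latent_corr = latent_corr,
      scales = scales, seed = as.integer(seed)
    ),
    class = "clinical_cohort_spec"
  )
}

#' @rdname clinical_cohort_spec
#' @export
default_clinical_corr <- function() {
  r <- matrix(0.75, 5, 5)
  diag(r) <- 1
  # adaptive functioning scores run opposite to the impairment scales
  r[1, -1] <- r[-1, 1] <- -0.7
  # visually scored EEG severity is only moderately tied to function
  r[5, 2:4] <- r[2:4, 5] <- 0.35
  r[1, 5] <- r[5, 1] <- -0.3
  dimnames(r) <- rep(list(c("vineland_abc", "gmfcs", "macs", "cfcs", "eeg_severity")), 2)
  r
}

#' @rdname clinical_cohort_spec
#' @export
default_clinical_scales <- function() {
  even <- function(k) stats::qnorm(seq_len(k - 1) / k)
  list(
    vineland_abc = list(levels = seq(25, 100, by = 5), thresholds = even(16)),
    gmfcs = list(levels = 1:5, thresholds = even(5)),
    macs = list(levels = 1:5, thresholds = even(5)),
    cfcs = list(levels = 1:5, thresholds = even(5)),
    eeg_severity = list(levels = 1:8, thresholds = even(8))
  )
}

#' Generate an ordinal clinical cohort via a Gaussian copula
#'
#' @param spec a [clinical_cohort_spec()]
#' @return data.frame with a `patient` column and one ordinal column per
#'   scale; the latent draws are stored in the `ground_truth` attribute
#' @export
gen_clinical_cohort <- function(spec) {
  stopifnot(inherits(spec, "clinical_cohort_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  p <- nrow(spec$latent_corr)
  e <- eigen(spec$latent_corr, symmetric = TRUE)
  rt <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), p) %*% t(e$vectors)
  z <- matrix(stats::rnorm(spec$n_patients * p), spec$n_patients, p) %*% rt
  out <- data.frame(patient = sprintf("P%02d", seq_len(spec$n_patients)))
  for (j in seq_len(p)) {
    sc <- spec$scales[[j]]
    lev <- sc$levels[findInterval(z[, j], sc$thresholds) + 1L]
    out[[names(spec$scales)[j]]] <- lev
  }
  attr(out, "ground_truth") <- list(latent = z, spec = spec)
  out
}
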