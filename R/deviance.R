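# Robust deviance quantification: Minimum Covariance Determinant centers and
# covariances in component-pair planes, Mahalanobis distances, leave-one-out
# jackknife for reference subjects, and age-matched centers.

#' Robust center and covariance by Minimum Covariance Determinant
#'
#' Fits the MCD location and scatter to two-dimensional scores via
#' `MASS::cov.rob`, using a support of `floor((n + 3) / 2)` observations
#' (the (n + 3) / (2n) support fraction) and the consistency-corrected
#' covariance. The estimator's stochastic subsampling is made reproducible
#' by seeding a local RNG stream.
#'
#' @param scores n x 2 numeric matrix of subject scores in one component
#'   pair plane (n >= 5)
#' @param kind label recorded with the fit: `"global"` or `"age_matched"`
#' @param target_age age (years) associated with an age-matched center
#' @param seed integer seed for the MCD subsampling
#' @return object of class `robust_center` with `center` (2-vector), `cov`
#'   (2 x 2), `support` (row indices used), `kind`, `n`
#' @export
fit_mcd <- function(scores, kind = c("global", "age_matched"), target_age = NULL, seed = 1L) {
  kind <- match.arg(kind)
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 5) stop(sprintf("MCD needs at least 5 observations, got %d", n))
  if (ncol(scores) != 2) stop("scores must have exactly 2 columns (one component pair)")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fit <- MASS::cov.rob(scores, method = "mcd", quantile.used = floor((n + 3) / 2))
  ev <- eigen(fit$cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) stop("singular robust scatter; scores are degenerate")
  structure(
    list(
      center = fit$center, cov = fit$cov, support = fit$best,
      kind = kind, target_age = target_age, n = n, seed = seed
    ),
    class = "robust_center"
  )
}

#' @export
print.robust_center <- function(x, ...) {
  cat(sprintf(
    "Robust %s center (MCD, n = %d, support %d): (%.3f, %.3f)\n",
    x$kind, x$n, length(x$support), x$center[1], x$center[2]
  ))
  invisible(x)
}

#' Mahalanobis distance to a robust center
#'
#' `sqrt((x - u)' Sigma^-1 (x - u))`: the square root is taken so the
#' distance has score units. Solved through the Cholesky factor of the
#' covariance.
#'
#' @param x 2-vector or n x 2 matrix of scores
#' @param center a [fit_mcd()] object, or a list with `center` and `cov`
#' @return nonnegative distance(s)
#' @export
mahal_dist <- function(x, center) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  S <- center$cov
  R <- tryCatch(chol(S), error = function(e) stop("singular covariance: cannot invert"))
  d <- sweep(x, 2, center$center)
  z <- backsolve(R, t(d), transpose = TRUE)
  sqrt(colSums(z^2))
}

#' Leave-one-out jackknife distances for the reference cohort
#'
#' For each reference subject the MCD is refitted on the remaining n - 1
#' scores and the held-out subject's Mahalanobis distance to that center is
#' computed, so no subject influences its own reference.
#'
#' @param scores n x 2 reference scores (n >= 6)
#' @param seed seed passed to each MCD refit
#' @return numeric vector of per-subject jackknife distances
#' @export
jackknife_md <- function(scores, seed = 1L) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 6) stop("jackknife needs at least 6 reference subjects")
  vapply(seq_len(n), function(i) {
    ctr <- tryCatch(
      fit_mcd(scores[-i, , drop = FALSE], seed = seed),
      error = function(e) stop(sprintf("MCD refit failed for fold %d: %s", i, conditionMessage(e)))
    )
    mahal_dist(scores[i, ], ctr)
  }, numeric(1))
}

#' Age-matched Mahalanobis distance
#'
#' Fits the MCD to the reference subjects whose age lies within `window`
#' years of the query age and returns the query's distance to that
#' age-matched center. If fewer than `min_n` reference subjects fall in the
#' window the call fails explicitly; the window is never widened silently,
#' since that would change the estimand.
#'
#' @param score query 2-vector of scores
#' @param age query age in years
#' @param ref_scores n x 2 reference scores
#' @param ref_ages reference ages (years)
#' @param window half-width of the age window in years (default 1, i.e.
#'   +/- 12 months)
#' @param min_n minimum number of reference subjects required (default 10)
#' @param seed seed for the MCD
#' @return list with `md` (distance), `n_support` (reference subjects in the
#'   window) and the fitted `center`
#' @export
age_matched_md <- function(score, age, ref_scores, ref_ages, window = 1,
                           min_n = 10, seed = 1L) {
  ref_scores <- as.matrix(ref_scores)
  if (length(ref_ages) != nrow(ref_scores)) stop("one age per reference subject required")
  idx <- which(abs(ref_ages - age) <= window)
  if (length(idx) < min_n) {
    stop(sprintf(
      "only %d reference subjects within +/- %g years of age %.2f (minimum %d)",
      length(idx), window, age, min_n
    ))
  }
  ctr <- fit_mcd(ref_scores[idx, , drop = FALSE],
    kind = "age_matched",
    target_age = age, seed = seed
  )
  list(md = unname(mahal_dist(score, ctr)), n_support = length(idx), center = ctr)
}

#' Deviance table across all component pairs
#'
#' For every component pair of a fitted normative space, computes each query
#' subject's Mahalanobis distance to the global reference center (`md_global`)
#' and, when ages are supplied, to the age-matched center (`md_age`).
#' Reference subjects, when included, get jackknifed global distances (each
#' excluded from its own reference fit).
#'
#' @param space a fitted [normative_space()]
#' @param ref reference feature data.frame or matrix (the cohort the space
#'   was fitted on)
#' @param query query feature data.frame or matrix (e.g. patients); may be
#'   `NULL` to tabulate the reference only
#' @param ref_ages,query_ages ages in years (taken from an `age_years`
#'   column when the inputs are generator data.frames)
#' @param pairs 2-column matrix of component pairs (default all [pc_pairs()])
#' @param window,min_n age-matching controls, see [age_matched_md()]
#' @param include_reference add jackknifed reference rows to the table
#' @param seed seed for all MCD fits
#' @return data.frame (subject, cohort, pc_pair, md_global, md_age,
#'   n_support_age)
#' @export
deviance_table <- function(space, ref, query = NULL, ref_ages = NULL, query_ages = NULL,
                           pairs = pc_pairs(space$n_components), window = 1, min_n = 10,
                           include_reference = FALSE, seed = 1L) {
  stopifnot(inherits(space, "normative_space"))
  if (is.null(ref_ages) && is.data.frame(ref) && "age_years" %in% names(ref)) {
    ref_ages <- ref$age_years
  }
  if (is.null(query_ages) && is.data.frame(query) && "age_years" %in% names(query)) {
    query_ages <- query$age_years
  }
  ref_scores <- predict(space, ref)
  query_scores <- if (!is.null(query)) predict(space, query) else NULL
  q_ids <- if (is.data.frame(query) && "subject" %in% names(query)) {
    query$subject
  } else if (!is.null(query_scores)) {
    sprintf("Q%03d", seq_len(nrow(query_scores)))
  }
  r_ids <- if (is.data.frame(ref) && "subject" %in% names(ref)) {
    ref$subject
  } else {
    sprintf("R%03d", seq_len(nrow(ref_scores)))
  }
  rows <- list()
  for (r in seq_len(nrow(pairs))) {
    pr <- pairs[r, ]
    lab <- sprintf("PC%d-PC%d", pr[1], pr[2])
    rs <- ref_scores[, pr, drop = FALSE]
    ctr <- fit_mcd(rs, seed = seed)
    if (!is.null(query_scores)) {
      qs <- query_scores[, pr, drop = FALSE]
      mg <- mahal_dist(qs, ctr)
      for (i in seq_len(nrow(qs))) {
        ma <- NA_real_
        ns <- NA_integer_
        if (!is.null(query_ages) && !is.null(ref_ages)) {
          am <- age_matched_md(qs[i, ], query_ages[i], rs, ref_ages,
            window = window, min_n = min_n, seed = seed
          )
          ma <- am$md
          ns <- am$n_support
        }
        rows[[length(rows) + 1L]] <- data.frame(
          subject = q_ids[i], cohort = "query", pc_pair = lab,
          md_global = unname(mg[i]), md_age = ma, n_support_age = ns
        )
      }
    }
    if (include_reference) {
      jk <- jackknife_md(rs, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = r_ids, cohort = "reference", pc_pair = lab,
        md_global = jk, md_age = NA_real_, n_support_age = NA_integer_
      )
    }
  }
  do.call(rbind, rows)
}
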