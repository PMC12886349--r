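# Inferential layer: paired Wilcoxon state comparisons with Shapiro-Wilk
# normality checks, Benjamini-Hochberg FDR within biomarker blocks, and
# Spearman correlations with permutation nulls and bootstrap intervals.

#' Paired Wilcoxon signed-rank comparison
#'
#' Compares paired distance vectors (e.g. the same subjects under two
#' recording states). Zero differences are dropped, per the signed-rank
#' convention; the effect size is `r = |Z| / sqrt(n)` with a
#' normal-approximation Z (tie-corrected) and n the number of pairs. The
#' Shapiro-Wilk p-value on the differences is reported alongside as the
#' normality check that motivates the non-parametric test. If all
#' differences are zero the result is flagged degenerate with p = 1, r = 0.
#'
#' @param a,b equal-length paired numeric vectors (n >= 6)
#' @return object of class `paired_test`: `statistic` (V), `p_value`,
#'   `effect_r`, `z`, `shapiro_p`, `n`, `n_nonzero`, `degenerate`
#' @export
paired_wilcoxon <- function(a, b) {
  if (length(a) != length(b)) stop("'a' and 'b' must be paired vectors of equal length")
  n <- length(a)
  if (n < 6) stop("need at least 6 pairs")
  d <- b - a
  shapiro_p <- tryCatch(stats::shapiro.test(d)$p.value, error = function(e) NA_real_)
  dz <- d[d != 0]
  m <- length(dz)
  if (m == 0) {
    return(structure(
      list(
        statistic = 0, p_value = 1, effect_r = 0, z = 0,
        shapiro_p = shapiro_p, n = n, n_nonzero = 0, degenerate = TRUE
      ),
      class = "paired_test"
    ))
  }
  r <- rank(abs(dz))
  V <- sum(r[dz > 0])
  mu <- m * (m + 1) / 4
  ties <- table(r)
  sig2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (V - mu) / sqrt(sig2)
  if (m <= 14) {
    # exact two-sided p by enumerating all 2^m sign assignments; valid under
    # ties because the observed (average) ranks are permuted as they are
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    Vperm <- drop(signs %*% r)
    p <- mean(abs(Vperm - mu) >= abs(V - mu) - 1e-9)
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(
    list(
      statistic = unname(V), p_value = p, effect_r = abs(z) / sqrt(n), z = z,
      shapiro_p = shapiro_p, n = n, n_nonzero = m, degenerate = FALSE
    ),
    class = "paired_test"
  )
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf(
    "Paired Wilcoxon signed-rank: V = %g, p = %.4g, r = %.3f (n = %d, %d nonzero; Shapiro-Wilk p = %.3g)%s\n",
    x$statistic, x$p_value, x$effect_r, x$n, x$n_nonzero, x$shapiro_p,
    if (x$degenerate) " [degenerate]" else ""
  ))
  invisible(x)
}

#' Benjamini-Hochberg FDR within blocks
#'
#' Applies the BH step-up adjustment independently within each block (e.g.
#' the 10 component-pair tests of one biomarker), never across blocks.
#'
#' @param p numeric p-values in `[0, 1]`
#' @param blocks block labels, recycled to `length(p)`; `NULL` for a single
#'   block
#' @return adjusted p-values in the original order
#' @export
bh_fdr <- function(p, blocks = NULL) {
  if (length(p) == 0) stop("empty block: no p-values to adjust")
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (is.null(blocks)) blocks <- rep(1L, length(p))
  blocks <- rep_len(blocks, length(p))
  out <- numeric(length(p))
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    out[idx] <- stats::p.adjust(p[idx], method = "BH")
  }
  out
}

#' Spearman correlation with permutation null and bootstrap interval
#'
#' Spearman's rho on average ranks; a two-tailed permutation p-value from
#' shuffling `y` with the add-one estimator
#' `p = (1 + #{|rho_perm| >= |rho_obs|}) / (1 + n_perm)` (so p is never
#' exactly zero), and an unstratified paired-bootstrap 95% percentile
#' confidence interval.
#'
#' @param x,y equal-length numeric vectors (n >= 5), neither constant
#' @param n_perm number of permutations (default 15000)
#' @param n_boot number of bootstrap resamples (default 15000)
#' @param seed integer seed for the local RNG stream
#' @param conf confidence level of the percentile interval
#' @return object of class `correlation_result`: `rho`, `ci` (length 2),
#'   `p_perm`, `n`, `n_perm`, `n_boot`, `seed`
#' @export
spearman_perm_boot <- function(x, y, n_perm = 15000, n_boot = 15000, seed = 1L,
                               conf = 0.95) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 5) stop("need at least 5 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input: correlation undefined")
  rho <- stats::cor(x, y, method = "spearman")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rx <- rank(x)
  ry <- rank(y)
  perm <- vapply(seq_len(n_perm), function(i) {
    stats::cor(rx, ry[sample.int(n)])
  }, numeric(1))
  p_perm <- (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (1 + n_perm)
  boot <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, replace = TRUE)
    if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0) {
      return(NA_real_)
    }
    stats::cor(x[idx], y[idx], method = "spearman")
  }, numeric(1))
  ci <- unname(stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE))
  structure(
    list(
      rho = rho, ci = ci, p_perm = p_perm, n = n,
      n_perm = n_perm, n_boot = n_boot, seed = seed
    ),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "Spearman rho = %.3f, 95%% CI [%.3f, %.3f], p_perm = %.4g (n = %d; %d perms, %d boots)\n",
    x$rho, x$ci[1], x$ci[2], x$p_perm, x$n, x$n_perm, x$n_boot
  ))
  invisible(x)
}

#' Correlate deviance with a clinical severity axis
#'
#' For one biomarker, distance kind and clinical axis, runs
#' [spearman_perm_boot()] between the per-pair Mahalanobis distances of a
#' [deviance_table()] and the patients' clinical component scores, and
#' adjusts the resulting p-values with Benjamini-Hochberg FDR within this
#' set of component-pair tests.
#'
#' @param dev a [deviance_table()] for the patients (cohort `"query"`)
#' @param clinical_scores named numeric vector of clinical axis scores, names
#'   matching `dev$subject`
#' @param distance which distance column to use: `"global"` or `"age"`
#' @param axis label recorded in the output (e.g. `"PC1_clin"`)
#' @param alpha FDR significance level (default 0.05)
#' @inheritParams spearman_perm_boot
#' @return data.frame, one row per component pair: `pc_pair`, `axis`,
#'   `distance`, `rho`, `ci_low`, `ci_high`, `p_perm`, `p_fdr`,
#'   `significant`, `n`
#' @export
correlate_deviance_clinical <- function(dev, clinical_scores, distance = c("global", "age"),
                                        axis = "PC1_clin", n_perm = 15000, n_boot = 15000,
                                        seed = 1L, alpha = 0.05) {
  distance <- match.arg(distance)
  col <- if (distance == "global") "md_global" else "md_age"
  dev <- dev[dev$cohort %in% "query", ]
  ids <- unique(dev$subject)
  unmatched <- setdiff(ids, names(clinical_scores))
  if (length(unmatched)) {
    stop("patient id(s) without clinical scores: ", paste(unmatched, collapse = ", "))
  }
  pairs <- unique(dev$pc_pair)
  rows <- lapply(seq_along(pairs), function(i) {
    sub <- dev[dev$pc_pair == pairs[i], ]
    r <- spearman_perm_boot(sub[[col]], unname(clinical_scores[sub$subject]),
      n_perm = n_perm, n_boot = n_boot, seed = seed + i
    )
    data.frame(
      pc_pair = pairs[i], axis = axis, distance = distance,
      rho = r$rho, ci_low = r$ci[1], ci_high = r$ci[2],
      p_perm = r$p_perm, n = r$n
    )
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(out$p_perm)
  out$significant <- out$p_fdr < alpha
  out[, c(
    "pc_pair", "axis", "distance", "rho", "ci_low", "ci_high",
    "p_perm", "p_fdr", "significant", "n"
  )]
}
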