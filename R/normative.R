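# Normative reference space: robust median/IQR scaling fitted on the
# reference cohort only, followed by sparse PCA of the scaled features.

#' Robust median/IQR scaler
#'
#' Fits per-feature median and interquartile range on reference rows only;
#' the frozen parameters are applied unchanged to any other cohort, so
#' patients are always expressed on the reference scale.
#'
#' @param x reference matrix or feature data.frame (subjects x features)
#' @return object of class `robust_scaler` with `center` (medians) and
#'   `scale` (IQRs)
#' @export
fit_scaler <- function(x) {
  x <- if (is.data.frame(x)) feature_values(x) else as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 reference rows to fit the scaler")
  ctr <- apply(x, 2, stats::median)
  scl <- apply(x, 2, stats::IQR)
  if (any(scl <= 0)) {
    bad <- colnames(x)[scl <= 0]
    if (is.null(bad)) bad <- which(scl <= 0)
    stop("zero interquartile range for feature(s): ", paste(bad, collapse = ", "))
  }
  structure(list(center = ctr, scale = scl), class = "robust_scaler")
}

#' @rdname fit_scaler
#' @param scaler a fitted `robust_scaler`
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "robust_scaler"))
  x <- if (is.data.frame(x)) feature_values(x) else as.matrix(x)
  if (ncol(x) != length(scaler$center)) stop("feature count does not match the fitted scaler")
  sweep(sweep(x, 2, scaler$center), 2, scaler$scale, "/")
}

soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

# Sequential rank-1 sparse PCA: soft-thresholded power iteration with
# projection deflation. The soft threshold for each component is
# (sparsity / 20) * max|X'u|, a calibration under which a sparsity
# parameter of 1.5 yields roughly 30-60% exact zeros on reference-like
# feature matrices, and sparsity -> 0 recovers classical PCA loadings.
sparse_pc1 <- function(X, sparsity, tol, max_iter) {
  sv <- svd(X, nu = 0, nv = 1)
  v <- sv$v[, 1]
  for (it in seq_len(max_iter)) {
    u <- drop(X %*% v)
    nu <- sqrt(sum(u^2))
    if (nu < 1e-12) break
    u <- u / nu
    z <- drop(crossprod(X, u))
    thr <- (sparsity / 20) * max(abs(z))
    vn <- soft_threshold(z, thr)
    if (all(vn == 0)) { # keep the single dominant feature
      vn <- numeric(length(z))
      vn[which.max(abs(z))] <- z[which.max(abs(z))]
    }
    vn <- vn / sqrt(sum(vn^2))
    if (sqrt(sum((vn - v)^2)) < tol || sqrt(sum((vn + v)^2)) < tol) {
      v <- vn
      break
    }
    v <- vn
  }
  v
}

#' Fit a sparse-PCA normative space on a reference cohort
#'
#' The fitting function of the normative model. Reference features are
#' scaled by their median and interquartile range (fitted here, on the
#' reference only) and a sparse principal component analysis is run on the
#' scaled matrix: components are extracted sequentially by soft-thresholded
#' power iterations with projection deflation, so many loadings are exactly
#' zero. Because sparse components are not exactly orthogonal, explained
#' variance is reported by the adjusted-variance convention (QR
#' orthogonalisation of the score matrix). Components are ordered by
#' explained variance and signed so each component's largest-magnitude
#' loading is positive.
#'
#' @param x reference cohort: feature data.frame (as produced by the
#'   generators) or numeric matrix, subjects x features; rows must outnumber
#'   features for stable covariance estimation
#' @param n_components number of components retained (default 5)
#' @param sparsity sparsity parameter (default 1.5); 0 gives classical PCA
#' @param tol convergence tolerance of the power iterations
#' @param max_iter maximum iterations per component
#' @return object of class `normative_space` with elements `loadings`
#'   (features x components, sparse), `explained_variance` (fractions),
#'   `cumulative_variance`, `scores` (reference scores), `scaler`,
#'   `sparsity`, `n_ref`
#' @examples
#' fm <- gen_cohort_features(tdc_cohort_spec(96, seed = 2))
#' sp <- normative_space(fm)
#' summary(sp)
#' @export
normative_space <- function(x, n_components = 5, sparsity = 1.5, tol = 1e-8,
                            max_iter = 2000) {
  xm <- if (is.data.frame(x)) feature_values(x) else as.matrix(x)
  n <- nrow(xm)
  p <- ncol(xm)
  if (n <= p) {
    stop(sprintf(
      "reference cohort (n = %d) must exceed the feature count (p = %d) for stable covariance estimation",
      n, p
    ))
  }
  if (n_components > p) stop("'n_components' cannot exceed the number of features")
  scaler <- fit_scaler(xm)
  Xs <- apply_scaler(scaler, xm)
  Xc <- sweep(Xs, 2, colMeans(Xs)) # center for the eigen-decomposition
  total_var <- sum(apply(Xc, 2, stats::var))
  W <- matrix(0, p, n_components, dimnames = list(colnames(xm), paste0("PC", seq_len(n_components))))
  Xk <- Xc
  for (k in seq_len(n_components)) {
    v <- sparse_pc1(Xk, sparsity, tol, max_iter)
    W[, k] <- v
    Xk <- Xk - (Xk %*% v) %*% t(v)
  }
  # sign convention: largest-magnitude loading positive
  for (k in seq_len(n_components)) {
    j <- which.max(abs(W[, k]))
    if (W[j, k] < 0) W[, k] <- -W[, k]
  }
  qrS <- qr(Xc %*% W)
  adj <- diag(qr.R(qrS))^2 / (n - 1)
  expl <- adj / total_var
  ord <- order(expl, decreasing = TRUE)
  W <- W[, ord, drop = FALSE]
  expl <- expl[ord]
  colnames(W) <- paste0("PC", seq_len(n_components))
  # scores are the scaled (median-0, IQR-1) rows times the loadings, with no
  # extra mean shift: a row at the reference median scores exactly zero
  S <- Xs %*% W
  structure(
    list(
      loadings = W,
      explained_variance = unname(expl),
      cumulative_variance = unname(cumsum(expl)),
      scores = S,
      scaler = scaler,
      sparsity = sparsity,
      n_components = n_components,
      n_ref = n,
      features = colnames(xm)
    ),
    class = "normative_space"
  )
}

#' @export
print.normative_space <- function(x, ...) {
  cat(sprintf(
    "Normative space: %d sparse components over %d features (n_ref = %d, sparsity = %g)\n",
    x$n_components, length(x$features), x$n_ref, x$sparsity
  ))
  cat(sprintf(
    "  explained variance: %s (cumulative %.1f%%)\n",
    paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
    100 * max(x$cumulative_variance)
  ))
  cat(sprintf(
    "  loading sparsity: %.0f%% exact zeros\n",
    100 * mean(x$loadings == 0)
  ))
  invisible(x)
}

#' @export
summary.normative_space <- function(object, ...) {
  tab <- data.frame(
    component = colnames(object$loadings),
    explained_pct = round(100 * object$explained_variance, 2),
    cumulative_pct = round(100 * object$cumulative_variance, 2),
    zero_loadings = colSums(object$loadings == 0),
    top_feature = apply(object$loadings, 2, function(v) object$features[which.max(abs(v))])
  )
  rownames(tab) <- NULL
  structure(list(table = tab, space = object), class = "summary.normative_space")
}

#' @export
print.summary.normative_space <- function(x, ...) {
  print(x$space)
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.normative_space <- function(object, ...) object$loadings

#' Project a cohort into the normative space
#'
#' Applies the frozen reference scaler and multiplies by the sparse loading
#' vectors; a subject at the reference feature-space median therefore scores
#' exactly zero on every component. With `pair`, returns
#' the two-dimensional scores of one component pair (10 distinct pairs exist
#' for 5 components, see [pc_pairs()]).
#'
#' @param object a fitted [normative_space()]
#' @param newdata feature data.frame or matrix (subjects x features)
#' @param pair optional length-2 integer vector of distinct component indices
#' @param ... unused
#' @return scores matrix (subjects x components, or x 2 when `pair` given)
#' @export
predict.normative_space <- function(object, newdata, pair = NULL, ...) {
  xm <- if (is.data.frame(newdata)) feature_values(newdata) else as.matrix(newdata)
  if (is.null(dim(xm))) xm <- matrix(xm, nrow = 1)
  S <- apply_scaler(object$scaler, xm) %*% object$loadings
  if (is.null(pair)) {
    return(S)
  }
  pair <- as.integer(pair)
  if (length(pair) != 2 || pair[1] == pair[2] ||
    any(pair < 1) || any(pair > object$n_components)) {
    stop("'pair' must be two distinct component indices within the fitted space")
  }
  S[, pair, drop = FALSE]
}

#' @export
plot.normative_space <- function(x, pair = c(1, 2), ...) {
  s <- x$scores[, pair, drop = FALSE]
  graphics::plot(s,
    xlab = colnames(s)[1], ylab = colnames(s)[2],
    main = "Reference cohort scores", ...
  )
  invisible(x)
}

#' All distinct component pairs
#'
#' @param n_components number of components (default 5, giving 10 pairs)
#' @return 2-column integer matrix, one row per unordered pair
#' @export
pc_pairs <- function(n_components = 5) {
  t(utils::combn(n_components, 2))
}
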