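#' Configuration for detrended fluctuation analysis
#'
#' @param fit_range length-2 numeric, smallest and largest window size in
#'   seconds over which the log-log line is fitted (default 2-20 s)
#' @param n_windows number of logarithmically spaced window sizes (>= 6)
#' @param overlap fractional overlap between consecutive windows in `[0, 1)`
#' @param order polynomial degree removed from each window (1 = linear)
#' @return object of class `dfa_config`
#' @export
dfa_config <- function(fit_range = c(2, 20), n_windows = 10, overlap = 0.5, order = 1) {
  stopifnot(length(fit_range) == 2, fit_range[1] > 0, fit_range[2] > fit_range[1])
  if (n_windows < 6) stop("need at least 6 window sizes for a stable log-log fit")
  if (overlap < 0 || overlap >= 1) stop("'overlap' must be in [0, 1)")
  if (!order %in% c(0, 1, 2)) stop("'order' must be 0, 1 or 2")
  structure(
    list(fit_range = fit_range, n_windows = n_windows, overlap = overlap, order = order),
    class = "dfa_config"
  )
}

#' Detrended fluctuation analysis exponent
#'
#' Quantifies long-range temporal correlations: the series is mean-centered
#' and cumulatively summed; for each window size the summed profile is split
#' into overlapping windows, a least-squares polynomial trend is removed per
#' window and the root-mean-square residual computed; the DFA exponent is the
#' slope of the least-squares line of log10 mean fluctuation against log10
#' window size. An exponent of 0.5 indicates an uncorrelated signal, values
#' above 0.5 persistent long-range correlations.
#'
#' Inputs shorter than 100 s trigger a warning (estimates become unreliable);
#' inputs shorter than 20 s are an error.
#'
#' @param x numeric series (e.g. a band amplitude envelope)
#' @param fs sampling rate in Hz
#' @param config a [dfa_config()]
#' @return object of class `dfa_result` with `exponent`, `fit_residual`
#'   (RMS residual of the log-log fit), `window_s` and `fluctuation`
#' @examples
#' set.seed(1)
#' dfa(rnorm(30000), fs = 250)$exponent # ~0.5
#' @export
dfa <- function(x, fs, config = dfa_config()) {
  x <- as.numeric(x)
  n <- length(x)
  dur <- n / fs
  if (dur < 20) stop(sprintf("series too short for DFA: %.1f s (< 20 s)", dur))
  if (dur < 100) {
    warning(sprintf("series of %.1f s is below the ~100 s needed for reliable DFA estimation", dur))
  }
  if (stats::sd(x) == 0) stop("zero-variance series: DFA undefined")
  win_s <- 10^seq(log10(config$fit_range[1]), log10(config$fit_range[2]),
    length.out = config$n_windows
  )
  win_n <- unique(pmax(as.integer(round(win_s * fs)), config$order + 2L))
  win_n <- win_n[win_n <= n / 2]
  if (length(win_n) < 6) {
    stop("fewer than 6 usable window sizes; extend the series or shrink the fit range")
  }
  y <- cumsum(x - mean(x))
  fluct <- vapply(win_n, function(w) {
    step <- max(1L, as.integer(floor(w * (1 - config$overlap))))
    starts <- seq(1L, n - w + 1L, by = step)
    idx <- seq_len(w)
    X <- if (config$order == 0) {
      matrix(1, w, 1)
    } else {
      cbind(1, stats::poly(idx, degree = config$order, raw = TRUE))
    }
    W <- vapply(starts, function(s) y[s:(s + w - 1L)], numeric(w))
    res <- as.matrix(stats::lm.fit(X, W)$residuals)
    mean(sqrt(colMeans(res^2)))
  }, numeric(1))
  lx <- log10(win_n / fs)
  ly <- log10(fluct)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  structure(
    list(
      exponent = unname(fit$coefficients[2]),
      fit_residual = sqrt(mean(fit$residuals^2)),
      window_s = win_n / fs,
      fluctuation = fluct,
      config = config
    ),
    class = "dfa_result"
  )
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf(
    "DFA exponent: %.3f (log-log RMS residual %.4f, %d window sizes %.2g-%.2g s)\n",
    x$exponent, x$fit_residual, length(x$window_s), min(x$window_s), max(x$window_s)
  ))
  invisible(x)
}

#' Band-wise DFA exponents for a block of parcel signals
#'
#' Batch entry point: for every parcel and every bin of the band scheme,
#' extracts the Hilbert amplitude envelope ([amplitude_envelope()]) and
#' estimates the DFA exponent.
#'
#' @param signals parcels x samples matrix
#' @param fs sampling rate in Hz
#' @param scheme a [band_scheme()]
#' @param config a [dfa_config()]
#' @param bands `"bins"` for all 11 bins or `"canonical"` for the 5 grouped
#'   bands
#' @return data.frame (parcel, bin or band, dfa_exponent, fit_residual)
#' @export
parcel_dfa <- function(signals, fs, scheme = band_scheme(), config = dfa_config(),
                       bands = c("bins", "canonical")) {
  bands <- match.arg(bands)
  signals <- as.matrix(signals)
  if (bands == "bins") {
    lo <- scheme$edges[-length(scheme$edges)]
    hi <- scheme$edges[-1]
    labels <- seq_len(scheme$n_bins)
  } else {
    lo <- vapply(scheme$band_edges, `[`, numeric(1), 1)
    hi <- vapply(scheme$band_edges, `[`, numeric(1), 2)
    labels <- names(scheme$band_edges)
  }
  rows <- list()
  for (i in seq_len(nrow(signals))) {
    for (b in seq_along(lo)) {
      env <- amplitude_envelope(signals[i, ], fs, c(lo[b], hi[b]))
      r <- suppressWarnings(dfa(env, fs, config))
      rows[[length(rows) + 1L]] <- data.frame(
        parcel = i, band = labels[b],
        dfa_exponent = r$exponent, fit_residual = r$fit_residual
      )
    }
  }
  do.call(rbind, rows)
}
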