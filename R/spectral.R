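#' Welch power spectral density
#'
#' Estimates the one-sided power spectral density with Welch's method:
#' Hamming-windowed segments of length equal to the FFT length (ten times the
#' sampling rate, giving a 0.1 Hz frequency grid), 50% overlap rounded down,
#' per-segment mean removal, and density normalisation such that the integral
#' of the PSD over frequency approximates the signal variance.
#'
#' @param x numeric signal (samples)
#' @param fs sampling rate in Hz
#' @return object of class `welch_psd` with `freq` (Hz, 0.1 Hz spacing),
#'   `power` (density in unit^2/Hz), `fs` and `n_segments`
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 20, by = 1 / 250))
#' p <- welch_psd(x, fs = 250)
#' p$freq[which.max(p$power)] # 10 Hz
#' @export
welch_psd <- function(x, fs) {
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    stop("'fs' must be a positive sampling rate in Hz")
  }
  x <- as.numeric(x)
  nfft <- as.integer(round(10 * fs))
  if (length(x) < nfft) {
    stop(sprintf(
      "signal too short for Welch estimation: need at least one segment of 10*fs = %d samples, got %d",
      nfft, length(x)
    ))
  }
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, nfft - 1) / (nfft - 1)) # Hamming
  step <- max(1L, as.integer(floor(nfft / 2)))
  starts <- seq(1L, length(x) - nfft + 1L, by = step)
  scale <- fs * sum(w^2)
  acc <- numeric(nfft)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1L)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  pxx <- acc / (length(starts) * scale)
  half <- nfft %/% 2L
  one_sided <- pxx[1:(half + 1L)]
  # double all bins except DC and Nyquist to conserve total power
  one_sided[2:half] <- 2 * one_sided[2:half]
  structure(
    list(
      freq = seq(0, half) * fs / nfft,
      power = one_sided,
      fs = fs,
      n_segments = length(starts)
    ),
    class = "welch_psd"
  )
}

#' @export
print.welch_psd <- function(x, ...) {
  cat(sprintf(
    "Welch PSD: %d frequencies, 0-%g Hz (df = %g Hz), %d segment(s)\n",
    length(x$freq), max(x$freq), x$freq[2] - x$freq[1], x$n_segments
  ))
  invisible(x)
}

# cumulative trapezoidal integral of psd evaluated at arbitrary frequencies,
# so band edges need not fall on the 0.1 Hz grid
psd_integral <- function(psd, lo, hi) {
  f <- psd$freq
  p <- psd$power
  cum <- c(0, cumsum(diff(f) * (p[-length(p)] + p[-1]) / 2))
  at <- function(q) stats::approx(f, cum, xout = q, rule = 2)$y
  at(hi) - at(lo)
}

#' Absolute and relative band powers from a PSD
#'
#' Integrates the PSD across each of the 11 bins of a [band_scheme()].
#' Absolute power is `10*log10` of the integrated band power (dB relative to
#' 1 unit^2); relative power is the band integral expressed as a percentage
#' of the total integrated power over the full 1-45 Hz range.
#'
#' Because the bins span 1-44.8 Hz while the total-power denominator covers
#' 1-45 Hz, relative powers sum to slightly below 100% by the (negligible for
#' 1/f-like spectra) 44.8-45 Hz sliver.
#'
#' @param psd a [welch_psd()] (or any list with `freq` and `power`)
#' @param scheme a [band_scheme()]
#' @return data.frame with columns `bin`, `band`, `f_lo`, `f_hi`,
#'   `absolute_db`, `relative_pct`
#' @export
band_powers <- function(psd, scheme = band_scheme()) {
  if (max(psd$freq) < scheme$range[2] || min(psd$freq) > scheme$range[1]) {
    stop("PSD must cover the 1-45 Hz range")
  }
  total <- psd_integral(psd, scheme$range[1], scheme$range[2])
  if (!is.finite(total) || total <= 0) {
    stop("total 1-45 Hz power is zero or non-finite; cannot form band powers")
  }
  lo <- scheme$edges[-length(scheme$edges)]
  hi <- scheme$edges[-1]
  bp <- mapply(function(l, h) psd_integral(psd, l, h), lo, hi)
  if (any(bp <= 0)) {
    bp <- pmax(bp, .Machine$double.xmin)
  }
  data.frame(
    bin = seq_len(scheme$n_bins),
    band = rep(names(scheme$groups), lengths(scheme$groups)),
    f_lo = lo,
    f_hi = hi,
    absolute_db = 10 * log10(bp),
    relative_pct = 100 * bp / total
  )
}

#' Band powers for a block of parcel signals
#'
#' Convenience batch entry: one Welch PSD and one [band_powers()] table per
#' parcel (matrix row).
#'
#' @param signals parcels x samples numeric matrix
#' @param fs sampling rate in Hz
#' @param scheme a [band_scheme()]
#' @return data.frame stacking per-parcel band-power rows with a `parcel`
#'   column
#' @export
parcel_band_powers <- function(signals, fs, scheme = band_scheme()) {
  signals <- as.matrix(signals)
  out <- lapply(seq_len(nrow(signals)), function(i) {
    bp <- band_powers(welch_psd(signals[i, ], fs), scheme)
    cbind(parcel = i, bp)
  })
  do.call(rbind, out)
}
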