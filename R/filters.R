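# Zero-phase FIR band-pass filtering and Hilbert amplitude envelopes.

# Hamming-windowed FIR band-pass. Transition width is 25% of the lower band
# edge; the classic Hamming design rule gives length ~ 3.3 * fs / tw.
design_bandpass <- function(band, fs) {
  lo <- band[1]
  hi <- band[2]
  if (lo <= 0 || hi >= fs / 2 || lo >= hi) {
    stop(sprintf("band [%g, %g] Hz must lie strictly inside (0, fs/2) = (0, %g)", lo, hi, fs / 2))
  }
  tw <- 0.25 * lo
  if ((hi - lo) < tw) {
    stop(sprintf(
      "band [%g, %g] Hz is too narrow for the designed filter (transition width %.2f Hz)",
      lo, hi, tw
    ))
  }
  n <- ceiling(3.3 * fs / tw)
  if (n %% 2 == 1) n <- n + 1 # even order -> odd length, type-I linear phase
  signal::fir1(n, c(lo, hi) / (fs / 2), type = "pass")
}

#' Zero-phase band-pass filter
#'
#' Applies a Hamming-window FIR band-pass forwards and backwards
#' (`signal::filtfilt`) so the output has zero phase shift.
#'
#' @param x numeric signal
#' @param fs sampling rate in Hz
#' @param band length-2 numeric, lower and upper passband edge in Hz
#' @return filtered signal, same length as `x`, with attribute
#'   `filter_length` (samples)
#' @export
band_filter <- function(x, fs, band) {
  h <- design_bandpass(band, fs)
  if (length(x) <= 3 * length(h)) {
    stop(sprintf(
      "signal too short to band-pass filter: %d samples for a filter of length %d",
      length(x), length(h)
    ))
  }
  y <- signal::filtfilt(as.numeric(h), 1, as.numeric(x))
  attr(y, "filter_length") <- length(h)
  y
}

# analytic signal via frequency-domain Hilbert transform
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(as.numeric(x)) * h, inverse = TRUE) / n
}

#' Band-limited amplitude envelope
#'
#' Band-pass filters the signal (zero-phase FIR) and takes the magnitude of
#' the analytic signal obtained by Hilbert transform. One filter length is
#' trimmed from each side to suppress filter and Hilbert edge transients.
#'
#' @inheritParams band_filter
#' @return the trimmed amplitude envelope (nonnegative numeric vector) with
#'   attribute `trimmed` (samples removed per side)
#' @examples
#' fs <- 250
#' x <- sin(2 * pi * 10 * seq(0, 20, by = 1 / fs))
#' env <- amplitude_envelope(x, fs, c(8, 13))
#' range(env) # ~1
#' @export
amplitude_envelope <- function(x, fs, band) {
  y <- band_filter(x, fs, band)
  trim <- attr(y, "filter_length")
  env <- Mod(analytic_signal(y))
  env <- env[(trim + 1):(length(env) - trim)]
  attr(env, "trimmed") <- trim
  env
}
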