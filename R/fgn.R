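#' Fractional Gaussian noise by circulant embedding
#'
#' Exact synthesis of stationary fractional Gaussian noise (FGN) with Hurst
#' parameter `H` using the Davies-Harte circulant-embedding method. The
#' autocovariance of FGN is
#' `gamma(k) = sd^2/2 * (|k+1|^(2H) - 2|k|^(2H) + |k-1|^(2H))`,
#' which is embedded in a circulant matrix whose eigenvalues (obtained by
#' FFT) are used to colour complex white noise. FGN is the increment process
#' of fractional Brownian motion, and its DFA exponent equals `H`, which
#' makes it an analytic oracle for long-range-correlation estimators.
#'
#' @param n number of samples
#' @param H Hurst parameter in (0, 1); 0.5 gives white noise
#' @param sd marginal standard deviation
#' @return numeric vector of length `n`
#' @examples
#' set.seed(7)
#' x <- fgn(10000, H = 0.8)
#' @export
fgn <- function(n, H, sd = 1) {
  stopifnot(n >= 2, H > 0, H < 1, sd > 0)
  if (abs(H - 0.5) < 1e-12) {
    return(stats::rnorm(n, sd = sd))
  }
  k <- 0:n
  g <- sd^2 / 2 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  row <- c(g[1:(n + 1)], g[n:2]) # circulant first row, length 2n
  m <- length(row)
  ev <- Re(stats::fft(row))
  ev[ev < 0 & ev > -1e-8] <- 0
  if (any(ev < 0)) stop("circulant embedding failed: negative eigenvalue")
  w <- complex(m)
  w[1] <- sqrt(ev[1]) * stats::rnorm(1)
  w[n + 1] <- sqrt(ev[n + 1]) * stats::rnorm(1)
  a <- stats::rnorm(n - 1)
  b <- stats::rnorm(n - 1)
  idx <- 2:n
  w[idx] <- sqrt(ev[idx] / 2) * complex(real = a, imaginary = b)
  w[m - idx + 2] <- Conj(w[idx])
  x <- Re(stats::fft(w)) / sqrt(m)
  x[1:n]
}
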