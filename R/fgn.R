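#' Theoretical autocovariance of fractional Gaussian noise
#'
#' Autocovariance at integer lag `k` of unit-variance fractional Gaussian
#' noise (fGn) with Hurst parameter `h`:
#' \eqn{\gamma(k) = \tfrac12(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})}.
#'
#' @param k integer lag(s), may be negative.
#' @param h Hurst parameter in (0, 1).
#' @return numeric vector of autocovariances.
#' @export
fgn_autocovariance <- function(k, h) {
  assert_scalar_number(h, "h", 0, 1, strict = TRUE)
  k <- abs(k)
  0.5 * (abs(k + 1)^(2 * h) - 2 * k^(2 * h) + abs(k - 1)^(2 * h))
}

# Circulant-embedding (Davies-Harte) synthesis using the *current* RNG
# stream. Returns a length-n series with the exact fGn autocovariance when
# the embedding is nonnegative definite; otherwise falls back to spectral
# synthesis with a warning.
fgn_core <- function(h, n) {
  if (n == 1L) return(stats::rnorm(1))
  m <- 2L * (n - 1L)
  g <- fgn_autocovariance(0:(n - 1L), h)
  circ <- c(g, g[(n - 1L):2L])
  lam <- Re(stats::fft(circ))
  tol <- -1e-8 * max(abs(lam))
  if (any(lam < tol)) {
    warning("Circulant embedding not nonnegative definite for h = ",
            format(h), "; falling back to spectral synthesis.", call. = FALSE)
    return(spectral_noise_core(n, beta = 2 * h - 1))
  }
  lam[lam < 0] <- 0
  w <- complex(length.out = m)
  # Real frequencies at DC and Nyquist; conjugate-symmetric pairs elsewhere.
  w[1L] <- sqrt(lam[1L]) * stats::rnorm(1)
  w[n] <- sqrt(lam[n]) * stats::rnorm(1)
  if (n > 2L) {
    j <- 2:(n - 1L)
    zr <- stats::rnorm(n - 2L)
    zi <- stats::rnorm(n - 2L)
    w[j] <- sqrt(lam[j] / 2) * complex(real = zr, imaginary = zi)
    w[m - j + 2L] <- Conj(w[j])
  }
  Re(stats::fft(w))[1:n] / sqrt(m)
}

# Fourier synthesis of noise with power spectral density ~ f^(-beta),
# standardized to zero mean, unit variance. Uses the current RNG stream.
spectral_noise_core <- function(n, beta) {
  n_freq <- floor(n / 2)
  amp <- (1:n_freq)^(-beta / 2)
  phase <- stats::runif(n_freq, 0, 2 * pi)
  half <- amp * exp(1i * phase)
  spec <- complex(length.out = n)
  spec[2:(n_freq + 1L)] <- half
  spec[n:(n - n_freq + 1L)] <- Conj(half)
  if (n %% 2 == 0) spec[n_freq + 1L] <- amp[n_freq] # real Nyquist bin
  x <- Re(stats::fft(spec, inverse = TRUE))
  as.numeric(scale(x))
}

#' Simulate fractional Gaussian noise
#'
#' Generates a stationary, zero-mean, unit-variance Gaussian series whose
#' autocovariance is that of fractional Gaussian noise with Hurst parameter
#' `h`, by circulant embedding (Davies-Harte). The embedding is exact; if it
#' ever fails to be nonnegative definite the generator falls back to spectral
#' synthesis (PSD ~ f^(1 - 2H)) with a warning.
#'
#' @param h Hurst parameter, strictly inside (0, 1). `h = 0.5` gives white
#'   noise.
#' @param length number of samples (>= 2).
#' @param seed optional integer; when given the series is a deterministic
#'   function of `(h, length, seed)` and the caller's RNG state is untouched.
#' @return numeric vector of length `length`.
#' @examples
#' x <- simulate_fgn(0.8, 512, seed = 1)
#' @export
simulate_fgn <- function(h, length, seed = NULL) {
  assert_scalar_number(h, "h", 0, 1, strict = TRUE)
  length <- assert_count(length, "length", min = 2L)
  with_seed(seed, fgn_core(h, length))
}

#' Simulate 1/f^beta ("colored") noise by spectral synthesis
#'
#' Builds a series whose power spectral density is proportional to
#' `f^(-beta)` using deterministic amplitudes and random uniform phases, then
#' standardizes it to zero mean and unit variance. `beta = 1` is pink noise,
#' for which the DFA exponent is (beta + 1) / 2 = 1.
#'
#' @param length number of samples.
#' @param beta spectral exponent (PSD ~ f^-beta).
#' @param seed optional integer seed.
#' @return numeric vector of length `length`.
#' @export
simulate_colored_noise <- function(length, beta = 1, seed = NULL) {
  length <- assert_count(length, "length", min = 4L)
  assert_scalar_number(beta, "beta", -2, 4)
  with_seed(seed, spectral_noise_core(length, beta))
}
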