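#' Autocovariance of fractional Gaussian noise
#'
#' Exact autocovariance function of unit-variance fractional Gaussian noise
#' (fGn), the stationary increment process of fractional Brownian motion:
#' \deqn{\gamma(k) = \frac{1}{2}\left(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}\right)}
#'
#' @param H Hurst exponent, in (0, 1).
#' @param lags integer vector of non-negative lags.
#' @return numeric vector of autocovariances, `gamma(0) = 1`.
#' @examples
#' fgn_acov(0.5, 0:3)  # white noise: 1, 0, 0, 0
#' @export
fgn_acov <- function(H, lags) {
  check_H(H)
  stopifnot(all(lags >= 0))
  k <- as.numeric(lags)
  0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
}

check_H <- function(H) {
  if (!is.numeric(H) || length(H) != 1L || !is.finite(H) || H <= 0 || H >= 1) {
    stop_invalid("Hurst exponent H must lie strictly in (0, 1); got ", format(H))
  }
  invisible(H)
}

#' Simulate fractional Gaussian noise
#'
#' Draws exact sample paths of zero-mean, unit-variance fGn. The default
#' sampler is circulant embedding (Davies-Harte): the covariance is embedded
#' in a circulant matrix whose eigenvalues are obtained by FFT, giving exact
#' draws in O(n log n). In the (for fGn, essentially theoretical) event that
#' the embedding has negative eigenvalues beyond tolerance, the sampler
#' falls back to the exact sequential Durbin-Levinson (Hosking) recursion
#' and emits a `boldhurst_embedding_fallback` warning.
#'
#' @param H Hurst exponent in (0, 1). `H = 0.5` is white noise; larger values
#'   give persistent (long-memory) series, smaller anti-persistent ones.
#' @param n series length (>= 2).
#' @param n_series number of independent series to draw.
#' @param seed optional integer seed; draws are reproducible given the seed
#'   and do not disturb the caller's RNG stream.
#' @return numeric matrix, `n` rows by `n_series` columns (a plain vector if
#'   `n_series = 1`).
#' @examples
#' x <- simulate_fgn(0.8, 512, seed = 1)
#' @export
simulate_fgn <- function(H, n, n_series = 1L, seed = NULL) {
  check_H(H)
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop_invalid("series length n must be >= 2")
  n_series <- as.integer(n_series)
  stopifnot(n_series >= 1L)
  out <- with_seed(seed, {
    lam <- fgn_embedding_eigenvalues(H, n)
    if (!is.null(lam)) {
      fgn_circulant_draw(lam, n, n_series)
    } else {
      warning(warningCondition(
        sprintf("circulant embedding not non-negative definite for H=%g, n=%d; using Durbin-Levinson sampler", H, n),
        class = "boldhurst_embedding_fallback"))
      vapply(seq_len(n_series), function(i) fgn_hosking(H, n), numeric(n))
    }
  })
  if (n_series == 1L) drop(out) else out
}

# Eigenvalues of the circulant embedding of the fGn covariance, or NULL when
# the embedding is not non-negative definite (then the caller must fall back).
fgn_embedding_eigenvalues <- function(H, n) {
  m <- 2L * (n - 1L)
  g <- fgn_acov(H, 0:(n - 1L))
  circ <- c(g, g[(n - 1L):2L])
  lam <- Re(stats::fft(circ))
  # tolerate tiny negative eigenvalues from floating-point round-off
  if (min(lam) < -1e-8 * max(lam)) return(NULL)
  pmax(lam, 0)
}

fgn_circulant_draw <- function(lam, n, n_series) {
  m <- length(lam)
  half <- m %/% 2L
  U <- matrix(stats::rnorm(m * n_series), m, n_series)
  W <- matrix(stats::rnorm(m * n_series), m, n_series)
  V <- matrix(complex(real = 0), m, n_series)
  V[1L, ] <- complex(real = U[1L, ])
  V[half + 1L, ] <- complex(real = U[half + 1L, ])
  idx <- seq.int(2L, half)
  V[idx, ] <- complex(
    real = U[idx, , drop = FALSE],
    imaginary = W[idx, , drop = FALSE]
  ) / sqrt(2)
  V[m + 2L - idx, ] <- Conj(V[idx, , drop = FALSE])
  Y <- stats::mvfft(sqrt(lam / m) * V)
  Re(Y[seq_len(n), , drop = FALSE])
}

# Exact sequential sampler via the Durbin-Levinson recursion (Hosking 1984).
# O(n^2); used only when the circulant embedding fails.
fgn_hosking <- function(H, n) {
  g <- fgn_acov(H, 0:n)
  x <- numeric(n)
  v <- g[1L]
  x[1L] <- stats::rnorm(1L) * sqrt(v)
  phi <- numeric(0)
  for (t in seq_len(n - 1L)) {
    phi_t <- if (t == 1L) {
      g[2L] / g[1L]
    } else {
      (g[t + 1L] - sum(phi * g[t:2L])) / v
    }
    phi <- c(phi - phi_t * rev(phi), phi_t)
    v <- v * (1 - phi_t^2)
    x[t + 1L] <- sum(phi * x[t:1L]) + stats::rnorm(1L) * sqrt(v)
  }
  x
}
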