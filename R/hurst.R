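# Rescaled-range (R/S) estimation of the Hurst exponent.
#
# For a window length n the series is cut into floor(N/n) non-overlapping
# segments; in each segment the cumulative deviations from the segment mean
# Z_t = sum_{i<=t} (x_i - xbar) give the range R = max Z - min Z, and S is
# the segment standard deviation (population convention, divide by n).
# mean R/S over segments, plotted against n on log-log axes, has slope H.

#' Log-spaced R/S window lengths
#'
#' Roughly `k` logarithmically spaced integer window lengths from
#' `min_scale` to `floor(N/2)`, deduplicated. At typical resting-state
#' lengths (N around 230) this yields stable segment counts at every scale.
#'
#' @param n_timepoints series length N.
#' @param k nominal number of scales.
#' @param min_scale smallest window length (>= 4).
#' @return increasing integer vector of window lengths.
#' @export
default_scales <- function(n_timepoints, k = 10L, min_scale = 10L) {
  hi <- n_timepoints %/% 2L
  if (hi < min_scale) stop_invalid("series too short for R/S scales (N=", n_timepoints, ")")
  unique(as.integer(round(2^seq(log2(min_scale), log2(hi), length.out = k))))
}

#' Rescaled-range curve of one series
#'
#' @param series numeric vector, length >= 2 * min(scales).
#' @param scales increasing integer window lengths, each >= 4.
#' @return object of class `rs_curve`: list with `scales`, `mean_rs`
#'   (mean R/S over segments with S > 0), and `n_segments_used`. Scales
#'   where every segment is constant are dropped.
#' @export
rs_curve <- function(series, scales) {
  res <- rs_curve_matrix(as.matrix(series), scales)
  keep <- res$n_segments_used[, 1L] > 0L
  if (!any(keep)) {
    stop(errorCondition("series is constant in every segment at every scale",
                        class = c("boldhurst_degenerate_input", "error")))
  }
  structure(list(
    scales = res$scales[keep],
    mean_rs = res$mean_rs[keep, 1L],
    n_segments_used = res$n_segments_used[keep, 1L]
  ), class = "rs_curve")
}

# Vectorised R/S over the columns of a timepoints x series matrix.
# Returns per-scale matrices; degenerate (all-constant) scales appear as
# NA mean_rs with zero segments used. Row loops keep every operation
# vectorised across segments*series, so cost is O(#scales * N * V).
rs_curve_matrix <- function(x, scales) {
  scales <- as.integer(scales)
  if (any(diff(scales) <= 0)) stop_invalid("scales must be strictly increasing")
  if (any(scales < 4L)) stop_invalid("every scale must be >= 4")
  N <- nrow(x); V <- ncol(x)
  if (N < 2L * scales[1L]) {
    stop_invalid("series length ", N, " must be >= 2 * min(scales) = ", 2L * scales[1L])
  }
  mean_rs <- matrix(NA_real_, length(scales), V)
  nseg <- matrix(0L, length(scales), V)
  for (si in seq_along(scales)) {
    s <- scales[si]
    m <- N %/% s
    A <- x[seq_len(m * s), , drop = FALSE]
    dim(A) <- c(s, m * V)                    # each column one segment
    A <- A - rep(colMeans(A), each = s)
    z <- A[1L, ]; mx <- z; mn <- z
    for (i in seq.int(2L, s)) {
      z <- z + A[i, ]
      mx <- pmax(mx, z)
      mn <- pmin(mn, z)
    }
    R <- mx - mn
    S <- sqrt(colMeans(A * A))               # population SD
    rs <- ifelse(S > 0, R / S, NA_real_)
    dim(rs) <- c(m, V)
    cnt <- as.integer(colSums(!is.na(rs)))
    mean_rs[si, ] <- colMeans(rs, na.rm = TRUE)
    mean_rs[si, cnt == 0L] <- NA_real_
    nseg[si, ] <- cnt
  }
  list(scales = scales, mean_rs = mean_rs, n_segments_used = nseg)
}

#' Expected rescaled range of white noise
#'
#' Closed-form finite-sample expectation of the R/S statistic for an i.i.d.
#' Gaussian series of length `n` (Anis & Lloyd 1976, with the
#' Peters small-sample factor (n - 1/2)/n):
#' \deqn{E[R/S]_n = \frac{n - 1/2}{n}\,
#'   \frac{\Gamma((n-1)/2)}{\sqrt{\pi}\,\Gamma(n/2)}
#'   \sum_{i=1}^{n-1} \sqrt{(n-i)/i}}
#' evaluated with `lgamma` so it is stable for large `n`.
#'
#' @param n integer vector of window lengths (>= 2).
#' @return numeric vector of expectations.
#' @export
expected_rs_white <- function(n) {
  vapply(as.integer(n), function(nn) {
    if (nn < 2L) stop_invalid("expected_rs_white needs n >= 2")
    i <- seq_len(nn - 1L)
    ((nn - 0.5) / nn) *
      exp(lgamma((nn - 1) / 2) - lgamma(nn / 2)) / sqrt(pi) *
      sum(sqrt((nn - i) / i))
  }, numeric(1))
}

#' Fit the Hurst exponent to an R/S curve
#'
#' Uncorrected: H is the ordinary-least-squares slope of
#' `log2(mean_rs)` against `log2(scale)` (the slope is base-invariant;
#' base 2 fixes the reported intercept). With `correction = TRUE` the
#' Anis-Lloyd white-noise expectation [expected_rs_white()] is subtracted
#' in the log domain and the fit is re-centred at 0.5:
#' `H = 0.5 + slope of (log2 mean_rs - log2 E[R/S])`. This removes the
#' finite-sample inflation of R/S that otherwise biases estimates of
#' uncorrelated and anti-persistent series upward.
#'
#' The spectral exponent `beta = 2H - 1` of the `1/f^beta` power-law is
#' reported alongside H.
#'
#' @param curve an [rs_curve()].
#' @param correction apply the Anis-Lloyd small-sample correction?
#' @return object of class `hurst_estimate`: list with `H`, `beta`,
#'   `intercept`, `r_squared`, `n_scales`, `corrected`.
#' @export
fit_hurst <- function(curve, correction = FALSE) {
  stopifnot(inherits(curve, "rs_curve"))
  ok <- is.finite(curve$mean_rs) & curve$mean_rs > 0
  if (sum(ok) < 3L) {
    stop(errorCondition("need >= 3 valid scales to fit H",
                        class = c("boldhurst_insufficient_scales", "error")))
  }
  fits <- fit_hurst_matrix(matrix(curve$mean_rs[ok]), curve$scales[ok], correction)
  structure(list(
    H = fits$H[1L], beta = 2 * fits$H[1L] - 1,
    intercept = fits$intercept[1L], r_squared = fits$r_squared[1L],
    n_scales = sum(ok), corrected = correction
  ), class = "hurst_estimate")
}

# Column-wise log-log OLS over a scales x series matrix of mean R/S.
# With correction, y is the log-domain excess over the white-noise
# expectation and the slope is re-centred at the white-noise H of 0.5.
fit_hurst_matrix <- function(mean_rs, scales, correction) {
  lx <- log2(scales)
  ly <- log2(mean_rs)
  if (correction) ly <- ly - log2(expected_rs_white(scales))
  lx_c <- lx - mean(lx)
  ly_c <- ly - rep(colMeans(ly), each = length(lx))
  slope <- colSums(lx_c * ly_c) / sum(lx_c^2)
  intercept <- colMeans(ly) - slope * mean(lx)
  ss_res <- colSums((ly_c - outer(lx_c, slope))^2)
  ss_tot <- colSums(ly_c^2)
  r2 <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, NA_real_)
  list(H = slope + if (correction) 0.5 else 0,
       intercept = intercept, r_squared = r2)
}

#' @export
print.hurst_estimate <- function(x, ...) {
  cat(sprintf("Hurst estimate: H = %.4f (beta = %.4f), %d scales, R^2 = %.3f%s\n",
              x$H, x$beta, x$n_scales, x$r_squared,
              if (x$corrected) ", Anis-Lloyd corrected" else ""))
  invisible(x)
}

#' Voxelwise Hurst-exponent map
#'
#' Estimates H at every masked voxel of a cleaned 4D volume. Degenerate
#' voxels (constant series, or fewer than 3 valid scales) are recorded as
#' `NA` in the map and flagged in the `undefined` mask rather than being
#' silently zeroed; their count is reported in a message.
#'
#' @param bold cleaned 4D array (x, y, z, time).
#' @param mask 3D logical (or 0/1) array of voxels to estimate.
#' @param scales window lengths; default [default_scales()] of the series
#'   length.
#' @param correction passed to the fit; see [fit_hurst()].
#' @return object of class `hurst_map`: list with `values` (3D array of H,
#'   `NA` outside the mask and at undefined voxels), `mask`, `undefined`
#'   (3D logical), `r_squared` (3D array), and `scales`.
#' @export
hurst_map <- function(bold, mask, scales = NULL, correction = FALSE) {
  stopifnot(length(dim(bold)) == 4L)
  d <- dim(bold)
  stopifnot(all(dim(mask) == d[1:3]))
  mask <- array(as.logical(mask), d[1:3])
  vox <- which(mask)
  if (!length(vox)) stop_invalid("mask is empty")
  if (is.null(scales)) scales <- default_scales(d[4])
  flat <- matrix(aperm(bold, c(4, 1, 2, 3)), nrow = d[4])[, vox, drop = FALSE]
  rs <- rs_curve_matrix(flat, scales)
  valid <- is.finite(rs$mean_rs) & rs$mean_rs > 0
  n_valid <- colSums(valid)
  est <- rep(NA_real_, length(vox))
  r2 <- rep(NA_real_, length(vox))
  full <- n_valid == length(scales)
  if (any(full)) {
    f <- fit_hurst_matrix(rs$mean_rs[, full, drop = FALSE], scales, correction)
    est[full] <- f$H
    r2[full] <- f$r_squared
  }
  partial <- which(!full & n_valid >= 3L)
  for (j in partial) {
    ok <- valid[, j]
    f <- fit_hurst_matrix(rs$mean_rs[ok, j, drop = FALSE], scales[ok], correction)
    est[j] <- f$H
    r2[j] <- f$r_squared
  }
  undef_idx <- vox[is.na(est)]
  if (length(undef_idx)) {
    message(length(undef_idx), " of ", length(vox),
            " masked voxels had degenerate series; flagged undefined")
  }
  values <- array(NA_real_, d[1:3]); values[vox] <- est
  r2map <- array(NA_real_, d[1:3]); r2map[vox] <- r2
  undefined <- array(FALSE, d[1:3]); undefined[undef_idx] <- TRUE
  structure(list(values = values, mask = mask, undefined = undefined,
                 r_squared = r2map, scales = scales, corrected = correction),
            class = "hurst_map")
}
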