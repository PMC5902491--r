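# Temporal cleaning of per-voxel BOLD series: linear detrend, nuisance
# regression, band-pass filter — applied in that order by clean_volume().
# All three steps are linear operators and preserve series length.

#' Remove a linear trend
#'
#' Fits and subtracts the least-squares line over the time index; the output
#' has zero mean and zero slope.
#'
#' @param series numeric vector (length >= 3) or matrix (timepoints x series).
#' @return residual series, same shape as the input.
#' @export
detrend_linear <- function(series) {
  x <- as.matrix(series)
  n <- nrow(x)
  if (n < 3L) stop_invalid("detrend_linear needs at least 3 timepoints")
  design <- cbind(1, seq_len(n))
  res <- stats::lm.fit(design, x)$residuals
  if (is.vector(series)) drop(res) else res
}

#' Regress out nuisance signals
#'
#' Returns the residuals of an ordinary least-squares regression of the
#' series on the confound set (plus an intercept, so residuals are
#' mean-centred). Residuals are orthogonal to every regressor. Typical
#' confounds are the six rigid-body motion parameters and mean white-matter
#' and ventricular signals.
#'
#' @param series numeric vector or matrix (timepoints x series).
#' @param confounds numeric matrix, timepoints x k, finite values.
#' @return residual series, same shape as `series`.
#' @export
regress_confounds <- function(series, confounds) {
  x <- as.matrix(series)
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != nrow(x)) {
    stop_invalid("confound rows (", nrow(confounds),
                 ") must match series length (", nrow(x), ")")
  }
  if (!all(is.finite(confounds))) stop_invalid("confounds must be finite")
  design <- cbind(`(intercept)` = 1, confounds)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[seq.int(qrd$rank + 1L, ncol(design))]]
    if (is.null(dropped)) dropped <- "<unnamed>"
    stop_invalid("confound design is rank deficient; collinear column(s): ",
                 paste(dropped, collapse = ", "))
  }
  res <- qr.resid(qrd, x)
  if (is.vector(series)) drop(res) else res
}

#' Zero-phase band-pass filter
#'
#' Ideal (frequency-domain boxcar) band-pass: Fourier coefficients whose
#' frequencies fall inside `[low_hz, high_hz]` (inclusive) are kept with
#' unit gain, all others zeroed. Being applied in the frequency domain the
#' filter is exactly zero-phase. The conventional resting-state band is
#' 0.01-0.10 Hz, suppressing slow scanner drift below and cardiac or
#' respiratory contamination above.
#'
#' @param series numeric vector or matrix (timepoints x series).
#' @param low_hz,high_hz band edges in Hz, `0 <= low < high <= 1/(2 tr)`.
#' @param tr repetition time (sampling interval), seconds.
#' @return filtered series, same shape as the input.
#' @export
bandpass <- function(series, low_hz, high_hz, tr) {
  if (tr <= 0) stop_invalid("tr must be positive")
  nyq <- 1 / (2 * tr)
  if (low_hz < 0 || low_hz >= high_hz) stop_invalid("need 0 <= low_hz < high_hz")
  if (high_hz > nyq + 1e-12) {
    stop_invalid("high_hz (", high_hz, ") exceeds the Nyquist frequency ",
                 format(nyq), " at tr=", tr)
  }
  x <- as.matrix(series)
  n <- nrow(x)
  freq <- seq_len(n) - 1L
  freq <- pmin(freq, n - freq) / (n * tr)  # two-sided frequency axis
  keep <- freq >= low_hz & freq <= high_hz
  xf <- stats::mvfft(x)
  xf[!keep, ] <- 0
  res <- Re(stats::mvfft(xf, inverse = TRUE)) / n
  if (is.vector(series)) drop(res) else res
}

#' Clean every voxel of a 4D volume
#'
#' Applies the temporal pipeline detrend -> nuisance regression -> band-pass
#' independently to each voxel inside the mask; voxels outside the mask are
#' zeroed. The stage order follows standard resting-state practice.
#'
#' @param bold 4D array (x, y, z, time).
#' @param mask 3D logical (or 0/1) array; default: all voxels.
#' @param confounds optional timepoints x k matrix for [regress_confounds()].
#' @param tr repetition time in seconds.
#' @param band length-2 numeric, band edges in Hz; `NULL` skips filtering.
#' @return cleaned 4D array of the same shape.
#' @export
clean_volume <- function(bold, mask = NULL, confounds = NULL,
                         tr = 2.0, band = c(0.01, 0.10)) {
  stopifnot(length(dim(bold)) == 4L)
  d <- dim(bold)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  stopifnot(all(dim(mask) == d[1:3]))
  mask <- array(as.logical(mask), d[1:3])
  vox <- which(mask)
  if (!length(vox)) stop_invalid("mask is empty")
  flat <- matrix(aperm(bold, c(4, 1, 2, 3)), nrow = d[4])
  x <- flat[, vox, drop = FALSE]
  x <- detrend_linear(x)
  if (!is.null(confounds)) x <- regress_confounds(x, confounds)
  if (!is.null(band)) x <- bandpass(x, band[1], band[2], tr)
  flat[] <- 0
  flat[, vox] <- x
  aperm(array(flat, dim = c(d[4], d[1:3])), c(2, 3, 4, 1))
}
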