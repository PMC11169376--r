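#' Canonical frequency bands
#'
#' The four band definitions used for feature extraction: theta (4-8 Hz),
#' alpha (8-13 Hz), beta (13-31 Hz), gamma (31-45 Hz).
#'
#' @return A tibble with columns `band`, `low_hz`, `high_hz`.
#' @export
band_specs <- function() .band_table()

resolve_band <- function(band) {
  bt <- .band_table()
  if (is.character(band)) {
    if (!band %in% bt$band) abort(sprintf("unknown band '%s'", band))
    r <- bt[bt$band == band, ]
    return(c(low = r$low_hz, high = r$high_hz))
  }
  if (is.numeric(band) && length(band) == 2) return(c(low = band[1], high = band[2]))
  abort("band must be a band name or numeric c(low_hz, high_hz)")
}

design_bandpass <- function(band, fs, order = 4) {
  e <- resolve_band(band)
  if (!(e["low"] > 0 && e["low"] < e["high"])) {
    abort(sprintf("invalid band edges [%g, %g]: need 0 < low < high", e["low"], e["high"]))
  }
  if (e["high"] >= fs / 2) {
    abort(sprintf("band edge %g Hz is at or above the Nyquist frequency %g Hz",
                  e["high"], fs / 2))
  }
  signal::butter(order, c(e["low"], e["high"]) / (fs / 2), type = "pass")
}

# One forward IIR pass (direct form II transposed) applied to every row of X
# simultaneously. Matches signal::filter() per row; vectorising across rows is
# what makes per-segment filtering of thousands of segments tractable.
iir_rows <- function(b, a, X) {
  b <- b / a[1]; a <- a / a[1]
  k <- length(b)
  Z <- matrix(0, nrow(X), k - 1)
  Y <- X
  for (t in seq_len(ncol(X))) {
    xt <- X[, t]
    yt <- b[1] * xt + Z[, 1]
    if (k > 2) for (j in seq_len(k - 2)) Z[, j] <- b[j + 1] * xt + Z[, j + 1] - a[j + 1] * yt
    Z[, k - 1] <- b[k] * xt - a[k] * yt
    Y[, t] <- yt
  }
  Y
}

# zero-phase: forward pass, time-reverse, forward pass, reverse back
zerophase_rows <- function(filt, X) {
  Y <- iir_rows(filt$b, filt$a, X)
  Y <- Y[, rev(seq_len(ncol(Y))), drop = FALSE]
  Y <- iir_rows(filt$b, filt$a, Y)
  Y[, rev(seq_len(ncol(Y))), drop = FALSE]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a fourth-order Butterworth band-pass filter forward and backward
#' (zero phase, so the four band-filtered versions of a segment stay
#' time-aligned) to each channel of a signal.
#'
#' @param x Numeric matrix (channels x time) or vector.
#' @param fs Sampling rate in Hz.
#' @param band Band name (`"theta"`, `"alpha"`, `"beta"`, `"gamma"`) or
#'   numeric `c(low_hz, high_hz)`.
#' @param order Filter order passed to [signal::butter()] (default 4).
#'
#' @return Filtered signal with the same shape as `x`.
#' @export
bandpass <- function(x, fs, band, order = 4) {
  filt <- design_bandpass(band, fs, order)
  if (is.matrix(x)) return(zerophase_rows(filt, x))
  drop(zerophase_rows(filt, matrix(x, nrow = 1)))
}
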