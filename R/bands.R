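# Band decomposition around the slow-varying DC (Sv DC) component:
# Sv DC = 0.01-0.5 Hz, isolated with the defining second-order
# Butterworth low-pass at 0.5 Hz; LF = 0.5-40 Hz; HF = 40-300 Hz.

SVDC_CUTOFF_HZ <- 0.5
LF_BAND_HZ <- c(0.5, 40)
HF_BAND_HZ <- c(40, 300)

#' Extract the slow-varying DC component
#'
#' Second-order Butterworth low-pass, cutoff 0.5 Hz, applied zero-phase
#' per channel. This is the defining filter of the Sv DC field: the
#' 0.01-0.5 Hz component of the (already high-pass-preprocessed)
#' signal.
#'
#' @param rec an [recording()] object, ideally already preprocessed
#'   with [broadband_filter()].
#' @param cutoff_hz low-pass cutoff in Hz (default 0.5).
#' @return numeric matrix of Sv DC series, same shape as
#'   `rec$samples`, labelled columns.
#' @export
extract_svdc <- function(rec, cutoff_hz = SVDC_CUTOFF_HZ) {
  stopifnot(inherits(rec, "svdc_recording"))
  if (rec$fs <= 1) stop("sampling rate must exceed 1 Hz")
  if (rec_duration(rec) < 10 / cutoff_hz)
    warning("record shorter than ", 10 / cutoff_hz,
            " s; edge effects may dominate the Sv DC estimate")
  filt <- design_butter(2, cutoff_hz, rec$fs, "low")
  pad <- settling_pad(rec$fs, cutoff_hz, nrow(rec$samples))
  filter_channels(rec$samples, filt, pad)
}

#' Extract a Butterworth band-pass component
#'
#' @param rec an [recording()] object.
#' @param low_hz,high_hz band edges in Hz.
#' @param order Butterworth order (default 4), applied zero-phase.
#' @return numeric matrix, same shape as `rec$samples`.
#' @export
extract_band <- function(rec, low_hz, high_hz, order = 4) {
  stopifnot(inherits(rec, "svdc_recording"))
  if (low_hz <= 0 || low_hz >= high_hz)
    stop("need 0 < low_hz < high_hz")
  filt <- design_butter(order, c(low_hz, high_hz), rec$fs, "pass")
  pad <- settling_pad(rec$fs, low_hz, nrow(rec$samples))
  filter_channels(rec$samples, filt, pad)
}

#' Piecewise-constant DC series
#'
#' The alternative definition of the slow DC component: the mean over
#' consecutive non-overlapping windows (2 s by default), held constant
#' within each window (stair-step series of the same length as the
#' input). Windows are anchored at t = 0; a final partial window uses
#' the partial mean. Over a long record this series tracks the
#' 0.01-0.5 Hz component closely.
#'
#' @param rec an [recording()] object.
#' @param window_s window length in seconds (default 2).
#' @return numeric matrix, same shape as `rec$samples`.
#' @export
piecewise_dc <- function(rec, window_s = 2) {
  stopifnot(inherits(rec, "svdc_recording"))
  if (window_s <= 0) stop("'window_s' must be positive")
  n <- nrow(rec$samples)
  if (n / rec$fs < window_s) stop("record shorter than one window")
  w <- as.integer(round(window_s * rec$fs))
  grp <- (seq_len(n) - 1L) %/% w
  out <- rec$samples
  for (j in seq_len(ncol(out))) {
    means <- tapply(rec$samples[, j], grp, mean)
    out[, j] <- means[as.character(grp)]
  }
  out
}

#' Decompose a recording into Sv DC, LF and HF components
#'
#' Assembles the three analysis bands: Sv DC (0.01-0.5 Hz, via
#' [extract_svdc()]), LF (0.5-40 Hz) and HF (40-300 Hz, both via
#' [extract_band()]).
#'
#' @param rec a preprocessed [recording()] object.
#' @param svdc_source optional recording the Sv DC component is
#'   extracted from instead of `rec` (e.g. the notch-only signal, so
#'   slow ictal shifts are not distorted by the broadband high-pass
#'   edge); energies stay consistent when left at the default.
#' @return an object of class `svdc_bandset`: list with per-band
#'   matrices `svdc`, `lf`, `hf`, the preprocessed `source` matrix,
#'   `fs`, `labels` and `band_edges`.
#' @export
decompose <- function(rec, svdc_source = rec) {
  stopifnot(inherits(rec, "svdc_recording"))
  structure(
    list(svdc = extract_svdc(svdc_source),
         lf = extract_band(rec, LF_BAND_HZ[1], LF_BAND_HZ[2]),
         hf = extract_band(rec, HF_BAND_HZ[1], HF_BAND_HZ[2]),
         source = rec$samples,
         fs = rec$fs,
         labels = rec$labels,
         band_edges = list(svdc = c(0.01, SVDC_CUTOFF_HZ),
                           lf = LF_BAND_HZ, hf = HF_BAND_HZ)),
    class = "svdc_bandset")
}

#' @export
print.svdc_bandset <- function(x, ...) {
  cat(sprintf("<svdc_bandset> %d leads x %d samples @ %g Hz\n",
              ncol(x$svdc), nrow(x$svdc), x$fs))
  cat("  bands: svdc 0.01-0.5 Hz | lf 0.5-40 Hz | hf 40-300 Hz\n")
  invisible(x)
}
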