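#' Line-noise notch filter
#'
#' Second-order IIR notch applied zero-phase to every channel.
#'
#' @param rec an [recording()] object.
#' @param freq_hz notch center frequency in Hz (default 50, mains).
#' @param quality_factor notch quality factor Q = f0 / bandwidth
#'   (default 30).
#' @return a filtered [recording()].
#' @export
notch_filter <- function(rec, freq_hz = 50, quality_factor = 30) {
  stopifnot(inherits(rec, "svdc_recording"))
  filt <- design_notch(freq_hz, rec$fs, quality_factor)
  pad <- settling_pad(rec$fs, freq_hz / quality_factor, nrow(rec$samples),
                      cap_s = 10)
  out <- rec
  out$samples <- filter_channels(rec$samples, filt, pad)
  out
}

#' Broadband Butterworth band-pass
#'
#' The fixed preprocessing band-pass retaining the analysis range
#' (default 0.01-300 Hz, 4th order), applied zero-phase. The 0 Hz
#' offset is removed asymptotically by the high-pass edge.
#'
#' @param rec an [recording()] object.
#' @param low_hz,high_hz band edges in Hz.
#' @param order Butterworth order (of the underlying design; the
#'   zero-phase application doubles the effective order).
#' @return a filtered [recording()].
#' @export
broadband_filter <- function(rec, low_hz = 0.01, high_hz = 300, order = 4) {
  stopifnot(inherits(rec, "svdc_recording"))
  if (low_hz <= 0 || low_hz >= high_hz)
    stop("need 0 < low_hz < high_hz")
  filt <- design_butter(order, c(low_hz, high_hz), rec$fs, "pass")
  pad <- settling_pad(rec$fs, low_hz, nrow(rec$samples))
  out <- rec
  out$samples <- filter_channels(rec$samples, filt, pad)
  out
}

#' Flag channels with numeric artifacts
#'
#' Implements the two numeric screening rules: a channel is flagged for
#' `drift` when its local baseline (moving median over `drift_min_s`)
#' stays outside +/- `drift_uV` for at least `drift_min_s` seconds, for
#' `discontinuity` when any sample-to-sample jump exceeds `jump_uV`,
#' and for `clipping` when it sits pinned at its amplitude extreme
#' (beyond `drift_uV`) for at least `clip_min_s` seconds.
#'
#' @param rec an [recording()] object.
#' @param drift_uV drift amplitude threshold in uV (default 100).
#' @param drift_min_s minimum duration of an offending baseline run in
#'   seconds (default 10).
#' @param jump_uV single-sample jump threshold in uV (default 500).
#' @param clip_min_s minimum saturation run in seconds (default 1).
#' @return a data frame with one row per channel: `label`, logical
#'   columns `drift`, `discontinuity`, `clipping`, `retained`, the
#'   combined `flags` string, and `drift_span_s`, the longest offending
#'   baseline run in seconds.
#' @export
flag_artifact_channels <- function(rec, drift_uV = 100, drift_min_s = 10,
                                   jump_uV = 500, clip_min_s = 1) {
  stopifnot(inherits(rec, "svdc_recording"))
  fs <- rec$fs
  n <- nrow(rec$samples)
  k <- as.integer(round(drift_min_s * fs))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (n %% 2L == 1L) n else n - 1L)
  res <- lapply(seq_len(ncol(rec$samples)), function(j) {
    x <- rec$samples[, j]
    base <- stats::runmed(x, k, endrule = "keep")
    out_of_band <- abs(base) > drift_uV
    span <- longest_run(out_of_band) / fs
    drift <- span >= drift_min_s
    disc <- if (n > 1L) max(abs(diff(x))) > jump_uV else FALSE
    clip_hi <- longest_run(x == max(x)) / fs
    clip_lo <- longest_run(x == min(x)) / fs
    clipping <- (clip_hi >= clip_min_s && max(x) >= drift_uV) ||
      (clip_lo >= clip_min_s && min(x) <= -drift_uV)
    data.frame(label = rec$labels[j], drift = drift,
               discontinuity = disc, clipping = clipping,
               drift_span_s = span, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$retained <- !(out$drift | out$discontinuity | out$clipping)
  out$flags <- apply(out[, c("drift", "discontinuity", "clipping")], 1,
                     function(f) paste(c("drift", "discontinuity",
                                         "clipping")[f], collapse = ","))
  out[, c("label", "drift", "discontinuity", "clipping", "retained",
          "flags", "drift_span_s")]
}

longest_run <- function(flag) {
  if (!any(flag)) return(0L)
  r <- rle(flag)
  max(r$lengths[r$values])
}
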