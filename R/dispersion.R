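# Cross-lead Sv DC dispersion: the spread of baseline-referenced Sv DC
# traces across leads, its ictal onset, and the interictal
# fluctuation-based lead ranking. Spread is the population SD (or
# scaled MAD) across leads of per-window mean Sv DC, so a common shift
# of the whole field leaves it unchanged while leads pulling apart
# raise it.

pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

window_means <- function(x, fs, window_s) {
  n <- length(x)
  w <- as.integer(round(window_s * fs))
  nw <- n %/% w
  if (nw < 1L) stop("record shorter than one window")
  idx <- seq_len(nw * w)
  grp <- rep(seq_len(nw), each = w)
  as.numeric(rowsum(x[idx], grp) / w)
}

#' Cross-lead Sv DC dispersion trace
#'
#' Each lead is referenced by its mean over `ref_interval`; the
#' dispersion at each `window_s` window is the cross-lead spread
#' (population SD, or scaled MAD) of the per-window mean referenced
#' Sv DC. Baseline statistics (median, MAD) of the trace are computed
#' over `ref_interval`.
#'
#' @param svdc per-lead Sv DC matrix (from [extract_svdc()] or a
#'   bandset's `$svdc`), one column per lead.
#' @param fs sampling rate in Hz.
#' @param ref_interval numeric `c(t0, t1)`: pre-ictal reference
#'   interval in seconds, preceding the span of interest.
#' @param window_s dispersion window in seconds (default 2, matching
#'   the piecewise-DC definition).
#' @param method `"sd"` (default) or `"mad"` for the cross-lead spread.
#' @param exclude lead labels to drop (artifact channels).
#' @param labels lead labels (default: column names of `svdc`).
#' @return an object of class `svdc_dispersion`: list with `times`
#'   (window centers, s), `values` (spread, uV), `baseline_median`,
#'   `baseline_mad`, `window_s`, `ref_interval`, `n_leads`.
#' @export
svdc_dispersion <- function(svdc, fs, ref_interval, window_s = 2,
                            method = c("sd", "mad"),
                            exclude = character(), labels = colnames(svdc)) {
  method <- match.arg(method)
  svdc <- as.matrix(svdc)
  if (!is.null(labels) && length(exclude))
    svdc <- svdc[, !(labels %in% exclude), drop = FALSE]
  if (ncol(svdc) < 2L)
    stop("dispersion needs at least 2 unflagged leads")
  if (length(ref_interval) != 2L || ref_interval[2] <= ref_interval[1])
    stop("'ref_interval' must be c(t0, t1) with t0 < t1")
  ref_idx <- sample_range(fs, ref_interval[1], ref_interval[2], nrow(svdc))
  refd <- sweep(svdc, 2, colMeans(svdc[ref_idx, , drop = FALSE]))
  wm <- sapply(seq_len(ncol(refd)), function(j)
    window_means(refd[, j], fs, window_s))
  if (is.null(dim(wm))) wm <- matrix(wm, nrow = 1L)
  spread_fun <- if (method == "sd") pop_sd else function(v) stats::mad(v)
  values <- apply(wm, 1, spread_fun)
  times <- (seq_len(nrow(wm)) - 0.5) * window_s
  in_ref <- times >= ref_interval[1] & times < ref_interval[2]
  if (!any(in_ref)) stop("'ref_interval' contains no dispersion windows")
  structure(list(times = times, values = values,
                 baseline_median = stats::median(values[in_ref]),
                 baseline_mad = stats::mad(values[in_ref]),
                 window_s = window_s, ref_interval = ref_interval,
                 n_leads = ncol(svdc), method = method),
            class = "svdc_dispersion")
}

#' @export
print.svdc_dispersion <- function(x, ...) {
  cat(sprintf(
    "<svdc_dispersion> %d windows of %g s, %d leads; baseline %.2f +/- %.2f uV (median +/- MAD)\n",
    length(x$times), x$window_s, x$n_leads, x$baseline_median,
    x$baseline_mad))
  invisible(x)
}

# Earliest time (window start) of a sustained run of `mask` windows,
# run length >= min_dur_s; NA when none.
sustained_onset <- function(times, mask, window_s, min_dur_s, from = -Inf) {
  usable <- times >= from
  mask <- mask & usable
  need <- max(1L, as.integer(ceiling(min_dur_s / window_s)))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= need)
  if (!length(hit)) return(NA_real_)
  times[starts[hit[1]]] - window_s / 2
}

#' Detect the onset (and peak/reconvergence) of Sv DC dispersion
#'
#' Onset is the earliest time where the dispersion trace exceeds
#' `baseline_median + k * baseline_MAD` sustained for at least
#' `min_dur_s`. The peak is the maximum of the trace after onset, and
#' reconvergence is the first sustained return to or below the
#' threshold after the peak.
#'
#' @param trace an [svdc_dispersion()] object.
#' @param k robust threshold multiplier (default 3).
#' @param min_dur_s minimum sustained duration in seconds (default 10).
#' @param floor_uv absolute threshold floor used when the baseline MAD
#'   is zero (default 1 uV), with a warning.
#' @param from only consider windows at or after this time (default:
#'   end of the reference interval).
#' @return list with `onset_s`, `peak_s`, `reconvergence_s` (each `NA`
#'   when not found) and the `threshold` used.
#' @export
detect_dispersion_onset <- function(trace, k = 3, min_dur_s = 10,
                                    floor_uv = 1,
                                    from = trace$ref_interval[2]) {
  stopifnot(inherits(trace, "svdc_dispersion"))
  mad <- trace$baseline_mad
  if (mad <= 0) {
    warning("baseline MAD is zero; using absolute floor of ", floor_uv,
            " uV above the baseline median")
    threshold <- trace$baseline_median + floor_uv
  } else {
    threshold <- trace$baseline_median + k * mad
  }
  above <- trace$values > threshold
  onset <- sustained_onset(trace$times, above, trace$window_s, min_dur_s,
                           from = from)
  peak_s <- NA_real_
  reconv <- NA_real_
  if (!is.na(onset)) {
    post <- trace$times >= onset
    peak_s <- trace$times[post][which.max(trace$values[post])]
    reconv <- sustained_onset(trace$times, !above, trace$window_s,
                              min_dur_s, from = peak_s)
  }
  list(onset_s = onset, peak_s = peak_s, reconvergence_s = reconv,
       threshold = threshold)
}

#' Detect band-activity onset from sliding energy
#'
#' Applies the same robust rule as [detect_dispersion_onset()] to the
#' cross-lead mean sliding energy of a band component: onset is the
#' earliest window where energy exceeds the reference-interval median
#' plus `k` MADs, sustained at least `min_dur_s`.
#'
#' @param band per-lead band matrix (e.g. a bandset's `$lf` or `$hf`)
#'   or a single numeric vector.
#' @param fs sampling rate in Hz.
#' @param ref_interval baseline interval `c(t0, t1)` in seconds.
#' @param window_s energy window (default 2 s).
#' @param k,min_dur_s threshold multiplier and sustained duration
#'   (defaults 3 and 10 s).
#' @param floor_frac when the baseline MAD is zero the threshold falls
#'   back to `(1 + floor_frac)` times the baseline median (default 1).
#' @param from only consider windows at or after this time (default:
#'   end of the reference interval).
#' @return onset time in seconds (window start), or `NA`.
#' @export
detect_band_onset <- function(band, fs, ref_interval, window_s = 2,
                              k = 3, min_dur_s = 10, floor_frac = 1,
                              from = ref_interval[2]) {
  if (!is.matrix(band)) band <- matrix(band, ncol = 1L)
  tr <- sliding_energy(band, fs, window_s = window_s, average = TRUE)
  in_ref <- tr$t0 >= ref_interval[1] & tr$t1 <= ref_interval[2]
  if (!any(in_ref)) stop("'ref_interval' contains no energy windows")
  base_med <- stats::median(tr$energy[in_ref])
  base_mad <- stats::mad(tr$energy[in_ref])
  if (base_mad <= 0) {
    warning("baseline energy MAD is zero; using relative floor")
    threshold <- base_med * (1 + floor_frac)
  } else {
    threshold <- base_med + k * base_mad
  }
  centers <- (tr$t0 + tr$t1) / 2
  onset <- sustained_onset(centers, tr$energy > threshold, window_s,
                           min_dur_s, from = from)
  if (is.na(onset)) NA_real_ else onset
}

#' Latency ordering of Sv DC dispersion vs LF/HF onsets
#'
#' @param svdc_onset,lf_onset,hf_onset onset times in seconds (`NA`
#'   when undetected).
#' @return list with `latency_svdc_to_lf`, `latency_svdc_to_hf`
#'   (seconds, `NA` when either onset is missing) and `svdc_first`,
#'   `TRUE` iff the Sv DC onset is present and strictly earliest among
#'   the detected onsets.
#' @export
onset_ordering <- function(svdc_onset, lf_onset, hf_onset) {
  if (all(is.na(c(svdc_onset, lf_onset, hf_onset))))
    stop("at least one onset must be present")
  lat_lf <- if (is.na(svdc_onset) || is.na(lf_onset)) NA_real_
            else lf_onset - svdc_onset
  lat_hf <- if (is.na(svdc_onset) || is.na(hf_onset)) NA_real_
            else hf_onset - svdc_onset
  others <- c(lf_onset, hf_onset)
  svdc_first <- !is.na(svdc_onset) &&
    all(is.na(others) | svdc_onset < others) &&
    any(!is.na(others))
  list(svdc_onset = svdc_onset, lf_onset = lf_onset, hf_onset = hf_onset,
       latency_svdc_to_lf = lat_lf, latency_svdc_to_hf = lat_hf,
       svdc_first = svdc_first)
}

#' Rank leads by interictal Sv DC fluctuation
#'
#' The shared trend is the cross-lead median Sv DC series; each lead's
#' score is the (population) SD of its residual around that trend.
#' Leads inside the epileptogenic zone fluctuate around the shared
#' trend more than leads outside it, so high scores flag candidate
#' epileptogenic leads. Series are reduced to `window_s` window means
#' first (the Sv DC band is limited to 0.5 Hz, so nothing is lost).
#'
#' @param svdc per-lead Sv DC matrix, one column per lead.
#' @param fs sampling rate in Hz.
#' @param labels lead labels (default: column names).
#' @param window_s averaging window before scoring (default 0.25 s).
#' @param exclude lead labels to drop.
#' @param min_span_s warn when the analyzed span is shorter than this
#'   (default 600 s = 10 min).
#' @return a data frame with columns `lead`, `score` (uV), `rank`
#'   (1 = largest fluctuation), sorted by rank.
#' @export
rank_leads_by_interictal_fluctuation <- function(svdc, fs,
                                                 labels = colnames(svdc),
                                                 window_s = 0.25,
                                                 exclude = character(),
                                                 min_span_s = 600) {
  svdc <- as.matrix(svdc)
  if (is.null(labels)) labels <- paste0("CH", seq_len(ncol(svdc)))
  keep <- !(labels %in% exclude)
  svdc <- svdc[, keep, drop = FALSE]
  labels <- labels[keep]
  if (ncol(svdc) < 3L)
    stop("lead ranking needs at least 3 leads (cross-lead median trend)")
  if (nrow(svdc) / fs < min_span_s)
    warning("interictal span shorter than ", min_span_s,
            " s; ranking may be unstable")
  wm <- sapply(seq_len(ncol(svdc)), function(j)
    window_means(svdc[, j], fs, window_s))
  if (is.null(dim(wm))) wm <- matrix(wm, nrow = 1L)
  # remove static per-lead offsets so only fluctuation is scored
  wm <- sweep(wm, 2, colMeans(wm))
  trend <- apply(wm, 1, stats::median)
  score <- apply(wm - trend, 2, pop_sd)
  out <- data.frame(lead = labels, score = score,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
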