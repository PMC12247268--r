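# Time-domain energy machinery: the energy-ratio statistic, lead-
# fraction summaries, sliding-window energy and the interictal
# active/stable phase rules. Energy is always the plain sum of squared
# samples (uV^2 per sample), never a spectral estimate.

#' Sum-of-squares energy of a window
#'
#' @param x numeric vector (one channel).
#' @param fs sampling rate in Hz.
#' @param t0,t1 half-open window `[t0, t1)` in seconds.
#' @return the energy `sum(x[i]^2)` over the window.
#' @export
segment_energy <- function(x, fs, t0, t1) {
  idx <- sample_range(fs, t0, t1, length(x))
  sum(x[idx]^2)
}

#' The 4-minute peri-ictal analysis window
#'
#' @param onset_s seizure onset in seconds.
#' @param pre_s,post_s seconds before/after onset (defaults 120/120,
#'   i.e. 2 min either side).
#' @param record_duration_s optional record length; the window is
#'   clipped to `[0, record_duration_s]` with a warning.
#' @return numeric `c(t0, t1)`.
#' @export
ictal_window <- function(onset_s, pre_s = 120, post_s = 120,
                         record_duration_s = NULL) {
  if (!is.finite(onset_s) || onset_s < 0)
    stop("seizure onset must be a non-negative time in seconds")
  if (!is.null(record_duration_s) && onset_s > record_duration_s)
    stop("seizure onset ", onset_s, " s lies outside the record (",
         record_duration_s, " s)")
  t0 <- onset_s - pre_s
  t1 <- onset_s + post_s
  if (!is.null(record_duration_s) && (t0 < 0 || t1 > record_duration_s)) {
    warning("peri-ictal window clipped to the record")
    t0 <- max(0, t0)
    t1 <- min(record_duration_s, t1)
  } else if (t0 < 0) {
    warning("peri-ictal window clipped at record start")
    t0 <- 0
  }
  c(t0, t1)
}

#' Per-lead band energies and energy ratios over a window
#'
#' For each lead, the energy of each band component over `[t0, t1)` is
#' divided by the energy of the full preprocessed signal over the same
#' window. Leads with zero total energy get `NA` ratios (undefined, not
#' zero).
#'
#' @param bands an `svdc_bandset` from [decompose()].
#' @param t0,t1 window in seconds.
#' @param exclude character vector of lead labels to drop (e.g.
#'   artifact-flagged channels).
#' @return a data frame with columns `lead`, `E_total`, `E_svdc`,
#'   `E_lf`, `E_hf`, `ratio_svdc`, `ratio_lf`, `ratio_hf`, plus
#'   attributes `window` and `n_excluded`.
#' @export
energy_ratio <- function(bands, t0, t1, exclude = character()) {
  stopifnot(inherits(bands, "svdc_bandset"))
  keep <- !(bands$labels %in% exclude)
  idx <- sample_range(bands$fs, t0, t1, nrow(bands$source))
  e_of <- function(m) colSums(m[idx, keep, drop = FALSE]^2)
  e_tot <- e_of(bands$source)
  e_svdc <- e_of(bands$svdc)
  e_lf <- e_of(bands$lf)
  e_hf <- e_of(bands$hf)
  denom <- ifelse(e_tot > 0, e_tot, NA_real_)
  out <- data.frame(lead = bands$labels[keep],
                    E_total = e_tot, E_svdc = e_svdc,
                    E_lf = e_lf, E_hf = e_hf,
                    ratio_svdc = e_svdc / denom,
                    ratio_lf = e_lf / denom,
                    ratio_hf = e_hf / denom,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "window") <- c(t0, t1)
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Fraction of leads whose Sv DC energy ratio reaches a threshold
#'
#' Pools Sv DC energy ratios (from one or several [energy_ratio()]
#' tables, or a bare numeric vector) and reports, for each threshold,
#' the count and fraction of leads at or above it. Comparisons are
#' inclusive (`>=`). Leads with undefined (missing) ratios are excluded
#' and reported separately.
#'
#' @param summaries a numeric vector of Sv DC ratios, an
#'   [energy_ratio()] data frame, or a list of such data frames.
#' @param thresholds numeric thresholds in `[0, 1]` (default 0.6, 0.9).
#' @return a data frame with columns `threshold`, `count`, `n_leads`,
#'   `fraction`, `pct`; attribute `n_missing` counts excluded leads.
#' @export
threshold_summary <- function(summaries, thresholds = c(0.6, 0.9)) {
  ratios <- pool_svdc_ratios(summaries)
  n_missing <- sum(is.na(ratios))
  ratios <- ratios[!is.na(ratios)]
  if (!length(ratios)) stop("no leads with defined Sv DC ratios")
  out <- data.frame(
    threshold = thresholds,
    count = vapply(thresholds, function(th) sum(ratios >= th), integer(1)),
    n_leads = length(ratios))
  out$fraction <- out$count / out$n_leads
  out$pct <- round(100 * out$fraction, 2)
  attr(out, "n_missing") <- n_missing
  out
}

pool_svdc_ratios <- function(summaries) {
  if (is.numeric(summaries)) return(as.numeric(summaries))
  if (is.data.frame(summaries)) return(summaries$ratio_svdc)
  if (is.list(summaries))
    return(unlist(lapply(summaries, pool_svdc_ratios), use.names = FALSE))
  stop("cannot extract Sv DC ratios from object of class ",
       paste(class(summaries), collapse = "/"))
}

#' Sliding-window energy trace
#'
#' Sum of squared samples over windows of `window_s` seconds advanced
#' by `hop_s` (default: non-overlapping, hop = window).
#'
#' @param x numeric vector (one channel), or a matrix (per-lead traces
#'   are computed column-wise and averaged across leads when
#'   `average = TRUE`).
#' @param fs sampling rate in Hz.
#' @param window_s window length in seconds (default 6).
#' @param hop_s hop between window starts (default `window_s`).
#' @param t_start time of the first sample in seconds (default 0).
#' @param average if `x` is a matrix, return the cross-lead mean energy
#'   trace (default `TRUE`); otherwise a matrix of traces.
#' @return a data frame with columns `t0`, `t1`, `energy` (or one
#'   energy column per lead), with attributes `window_s`, `hop_s`.
#' @export
sliding_energy <- function(x, fs, window_s = 6, hop_s = window_s,
                           t_start = 0, average = TRUE) {
  if (window_s <= 0 || hop_s <= 0) stop("window_s and hop_s must be positive")
  if (is.matrix(x)) {
    traces <- sapply(seq_len(ncol(x)), function(j)
      sliding_energy(x[, j], fs, window_s, hop_s, t_start)$energy)
    if (is.null(dim(traces))) traces <- matrix(traces, nrow = 1L)
    colnames(traces) <- colnames(x)
    base <- sliding_energy(x[, 1], fs, window_s, hop_s, t_start)
    if (average) {
      base$energy <- rowMeans(traces)
    } else {
      base$energy <- NULL
      base <- cbind(base, as.data.frame(traces))
    }
    attr(base, "window_s") <- window_s
    attr(base, "hop_s") <- hop_s
    return(base)
  }
  n <- length(x)
  w <- as.integer(round(window_s * fs))
  h <- as.integer(round(hop_s * fs))
  if (n < w) stop("record shorter than one window")
  cs <- cumsum(c(0, x^2))
  starts <- seq.int(1L, n - w + 1L, by = h)
  out <- data.frame(t0 = t_start + (starts - 1L) / fs,
                    t1 = t_start + (starts - 1L + w) / fs,
                    energy = cs[starts + w] - cs[starts])
  attr(out, "window_s") <- window_s
  attr(out, "hop_s") <- hop_s
  out
}

#' Baseline energy from the preceding hour
#'
#' Mean sliding-window energy over the hour before `t_obs` (clipped to
#' the available history with a warning).
#'
#' @param x numeric vector (one channel).
#' @param fs sampling rate in Hz.
#' @param t_obs start of the observation period in seconds.
#' @param window_s,hop_s sliding-window parameters (defaults 6 s,
#'   non-overlapping).
#' @return the baseline energy (uV^2 per window).
#' @export
preceding_hour_baseline <- function(x, fs, t_obs, window_s = 6,
                                    hop_s = window_s) {
  if (t_obs <= 0) stop("no history before t_obs = ", t_obs, " s")
  t0 <- t_obs - 3600
  if (t0 < 0) {
    warning("less than 1 h of history before t_obs; baseline uses ",
            round(t_obs), " s")
    t0 <- 0
  }
  idx <- sample_range(fs, t0, t_obs, length(x))
  if (length(idx) < window_s * fs)
    stop("history before t_obs is shorter than one window")
  tr <- sliding_energy(x[idx], fs, window_s, hop_s, t_start = t0)
  mean(tr$energy)
}

#' Detect interictal active phases from an energy trace
#'
#' Active periods are maximal runs of windows whose energy is at least
#' `(1 + increase)` times the baseline (the default `increase = 1`
#' is the 100%-over-baseline rule). Runs separated by less than
#' `merge_gap_s` are merged, then runs shorter than `min_dur_s` are
#' dropped. The stable phase is the complement over the analyzed span.
#'
#' @param trace a [sliding_energy()] data frame.
#' @param baseline baseline energy (> 0), e.g. from
#'   [preceding_hour_baseline()].
#' @param increase fractional increase over baseline defining activity
#'   (default 1.0 = 100%); the comparison is inclusive.
#' @param min_dur_s minimum duration of an active interval (default 12).
#' @param merge_gap_s merge active runs closer than this (default 6).
#' @return an object of class `svdc_phases`: list with `active` and
#'   `stable` interval data frames (`t0`, `t1`), `baseline`,
#'   `window_s`, `criterion`, and the per-window `active_mask`.
#' @export
detect_active_phases <- function(trace, baseline, increase = 1.0,
                                 min_dur_s = 12, merge_gap_s = 6) {
  if (!is.finite(baseline) || baseline <= 0)
    stop("'baseline' must be a positive energy")
  mask <- trace$energy >= (1 + increase) * baseline
  active <- mask_to_intervals(trace, mask)
  active <- merge_intervals(active, merge_gap_s)
  active <- active[active$t1 - active$t0 >= min_dur_s, , drop = FALSE]
  span <- c(min(trace$t0), max(trace$t1))
  stable <- complement_intervals(active, span)
  structure(list(active = active, stable = stable, baseline = baseline,
                 window_s = attr(trace, "window_s"),
                 criterion = increase, active_mask = mask, span = span),
            class = "svdc_phases")
}

mask_to_intervals <- function(trace, mask) {
  if (!any(mask))
    return(data.frame(t0 = numeric(0), t1 = numeric(0)))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(t0 = trace$t0[starts[keep]], t1 = trace$t1[ends[keep]])
}

merge_intervals <- function(iv, gap_s) {
  if (nrow(iv) < 2L) return(iv)
  iv <- iv[order(iv$t0), , drop = FALSE]
  out_t0 <- iv$t0[1]
  out_t1 <- iv$t1[1]
  for (i in 2:nrow(iv)) {
    if (iv$t0[i] - out_t1[length(out_t1)] < gap_s) {
      out_t1[length(out_t1)] <- max(out_t1[length(out_t1)], iv$t1[i])
    } else {
      out_t0 <- c(out_t0, iv$t0[i])
      out_t1 <- c(out_t1, iv$t1[i])
    }
  }
  data.frame(t0 = out_t0, t1 = out_t1)
}

complement_intervals <- function(iv, span) {
  if (nrow(iv) == 0L) return(data.frame(t0 = span[1], t1 = span[2]))
  iv <- iv[order(iv$t0), , drop = FALSE]
  t0 <- c(span[1], iv$t1)
  t1 <- c(iv$t0, span[2])
  keep <- t1 - t0 > 1e-9
  data.frame(t0 = t0[keep], t1 = t1[keep])
}

#' Jaccard overlap of two interval sets
#'
#' Total length of the intersection divided by total length of the
#' union; 1 when both sets cover identical time, 0 when disjoint.
#'
#' @param a,b interval data frames with columns `t0`, `t1`.
#' @return a number in `[0, 1]` (`NA` if both sets are empty).
#' @export
interval_jaccard <- function(a, b) {
  norm <- function(iv) {
    if (nrow(iv) == 0L) return(iv)
    merge_intervals(iv[order(iv$t0), , drop = FALSE], 0)
  }
  a <- norm(a)
  b <- norm(b)
  len <- function(iv) if (nrow(iv)) sum(iv$t1 - iv$t0) else 0
  inter <- 0
  if (nrow(a) && nrow(b)) {
    for (i in seq_len(nrow(a))) {
      lo <- pmax(a$t0[i], b$t0)
      hi <- pmin(a$t1[i], b$t1)
      inter <- inter + sum(pmax(0, hi - lo))
    }
  }
  uni <- len(a) + len(b) - inter
  if (uni <= 0) return(NA_real_)
  inter / uni
}

#' Compare stable- and active-phase window energies
#'
#' Two-sided Wilcoxon rank-sum test on the two samples of window
#' energies.
#'
#' @param stable_energy,active_energy numeric vectors of window
#'   energies.
#' @return list with `statistic` (rank-sum W), `p_value`,
#'   `median_stable`, `median_active`, `active_higher` (logical), and
#'   sample sizes. With fewer than 3 windows in either sample the
#'   p-value is reported missing with a warning.
#' @export
compare_phase_energy <- function(stable_energy, active_energy) {
  if (!length(stable_energy) || !length(active_energy))
    stop("both samples must be non-empty")
  med_s <- stats::median(stable_energy)
  med_a <- stats::median(active_energy)
  if (length(stable_energy) < 3L || length(active_energy) < 3L) {
    warning("fewer than 3 windows in a phase; p-value not computed")
    return(list(statistic = NA_real_, p_value = NA_real_,
                median_stable = med_s, median_active = med_a,
                active_higher = med_a > med_s,
                n_stable = length(stable_energy),
                n_active = length(active_energy)))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(active_energy, stable_energy, exact = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median_stable = med_s, median_active = med_a,
       active_higher = med_a > med_s,
       n_stable = length(stable_energy),
       n_active = length(active_energy))
}
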