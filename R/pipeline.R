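# End-to-end ictal and interictal analyses. Each report value is the
# direct output of one module operation; the pipeline only wires them
# together, so reports are reproducible from (recording, parameters)
# with no randomness of their own.

default_ictal_params <- function() {
  list(notch_hz = 50, band = c(0.01, 300), band_order = 4,
       pre_s = 120, post_s = 120,
       ref_gap_s = 30, ref_len_s = 120,
       disp_window_s = 2, disp_k = 3, disp_min_dur_s = 10,
       onset_window_s = 2, onset_k = 3, onset_min_dur_s = 10,
       seizure_duration_s = 90, n_stages = 3, stage_band = "hf",
       thresholds = c(0.6, 0.9),
       drift_uV = 100, drift_min_s = 10, jump_uV = 500,
       corr_pair = NULL)
}

preprocess_recording <- function(rec, params, flag_until_s = NULL) {
  notched <- notch_filter(rec, params$notch_hz)
  clean <- broadband_filter(notched, params$band[1], params$band[2],
                            params$band_order)
  # screening runs on the notched signal: the broadband high-pass
  # removes exactly the baseline offsets the drift rule looks for
  flag_rec <- notched
  if (!is.null(flag_until_s) && flag_until_s > 1) {
    idx <- sample_range(notched$fs, 0, flag_until_s, nrow(notched$samples))
    flag_rec <- recording(notched$samples[idx, , drop = FALSE],
                          notched$fs, notched$labels)
  }
  quality <- flag_artifact_channels(flag_rec, drift_uV = params$drift_uV,
                                    drift_min_s = params$drift_min_s,
                                    jump_uV = params$jump_uV)
  list(clean = clean, notched = notched, quality = quality,
       excluded = quality$label[!quality$retained])
}

#' Run the full ictal analysis on one recording
#'
#' Preprocesses (notch + broadband band-pass, numeric artifact
#' flagging on the pre-ictal segment), decomposes into Sv DC/LF/HF,
#' and computes: the 4-min peri-ictal energy summary with
#' threshold-fraction statistics, the cross-lead Sv DC dispersion
#' trace with onset/peak/reconvergence, LF and HF activity onsets, the
#' onset-ordering latency report, and staged cross-correlation and PLV
#' across the seizure span.
#'
#' @param rec an [recording()] object.
#' @param onset_s seizure onset in seconds (default: first "seizure"
#'   annotation).
#' @param params named list overriding entries of the default
#'   parameter set (see Details).
#' @details Default parameters: 50 Hz notch; 0.01-300 Hz 4th-order
#'   band-pass; 2 min before/after onset for the energy window; a
#'   120-s reference interval ending 30 s before the energy window;
#'   dispersion/onset rule median + 3 MAD sustained 10 s on 2-s
#'   windows; staged analyses over `onset + c(0, 90)` s in 3 equal
#'   stages on the HF band; the correlation pair defaults to the first
#'   and last lead in spatial order.
#' @return list of class `svdc_ictal_report`: `quality`, `excluded`,
#'   `window`, `energy` (per-lead [energy_ratio()] table),
#'   `threshold_summary`, `dispersion` (trace), `events`
#'   (onset/peak/reconvergence), `lf_onset_s`, `hf_onset_s`,
#'   `ordering`, `staged_correlation`, `staged_plv`, `params`.
#' @export
run_ictal_analysis <- function(rec, onset_s = NULL, params = list()) {
  p <- utils::modifyList(default_ictal_params(), params)
  if (is.null(onset_s)) {
    sz <- rec$annotations[rec$annotations$label == "seizure", , drop = FALSE]
    if (!nrow(sz)) stop("no seizure onset given or annotated")
    onset_s <- sz$onset_s[1]
  }
  dur <- rec_duration(rec)
  win <- ictal_window(onset_s, p$pre_s, p$post_s, record_duration_s = dur)
  ref <- c(max(0, win[1] - p$ref_gap_s - p$ref_len_s),
           max(0, win[1] - p$ref_gap_s))
  if (ref[2] - ref[1] < 2 * p$disp_window_s)
    stop("not enough pre-ictal data for a reference interval")

  pre <- preprocess_recording(rec, p, flag_until_s = win[1])
  if (length(pre$excluded) == ncol(rec$samples))
    stop("all channels flagged as artifacts; nothing to analyze")
  bands <- decompose(pre$clean)

  energy <- energy_ratio(bands, win[1], win[2], exclude = pre$excluded)
  thr <- threshold_summary(energy, thresholds = p$thresholds)

  # timing analyses use the Sv DC of the notch-only signal: the 0.5 Hz
  # low-pass applied to the original signal preserves the slow ictal
  # shift, which the broadband high-pass edge would smear in time
  svdc_timing <- extract_svdc(pre$notched)
  disp <- svdc_dispersion(svdc_timing, bands$fs, ref_interval = ref,
                          window_s = p$disp_window_s,
                          exclude = pre$excluded, labels = bands$labels)
  events <- detect_dispersion_onset(disp, k = p$disp_k,
                                    min_dur_s = p$disp_min_dur_s)
  keep <- !(bands$labels %in% pre$excluded)
  lf_onset <- detect_band_onset(bands$lf[, keep, drop = FALSE], bands$fs,
                                ref_interval = ref,
                                window_s = p$onset_window_s,
                                k = p$onset_k,
                                min_dur_s = p$onset_min_dur_s)
  hf_onset <- detect_band_onset(bands$hf[, keep, drop = FALSE], bands$fs,
                                ref_interval = ref,
                                window_s = p$onset_window_s,
                                k = p$onset_k,
                                min_dur_s = p$onset_min_dur_s)
  ordering <- onset_ordering(events$onset_s, lf_onset, hf_onset)

  span <- c(onset_s, min(onset_s + p$seizure_duration_s, dur))
  pair <- p$corr_pair
  if (is.null(pair)) {
    ordk <- lead_order(bands$labels[keep])
    lbl <- bands$labels[keep][ordk]
    pair <- c(lbl[1], lbl[length(lbl)])
  }
  bm <- bands[[p$stage_band]]
  staged_cc <- staged_cross_correlation(
    bm[, match(pair[1], bands$labels)], bm[, match(pair[2], bands$labels)],
    bands$fs, span, n_stages = p$n_stages)
  staged_sync <- staged_plv(bands, span, n_stages = p$n_stages,
                            band = p$stage_band, exclude = pre$excluded)

  structure(list(onset_s = onset_s, window = win, ref_interval = ref,
                 quality = pre$quality, excluded = pre$excluded,
                 energy = energy, threshold_summary = thr,
                 dispersion = disp, events = events,
                 lf_onset_s = lf_onset, hf_onset_s = hf_onset,
                 ordering = ordering, corr_pair = pair,
                 staged_correlation = staged_cc,
                 staged_plv = staged_sync, params = p),
            class = "svdc_ictal_report")
}

default_interictal_params <- function() {
  list(notch_hz = 50, band = c(0.01, 300), band_order = 4,
       window_s = 6, increase = 1.0, min_dur_s = 12, merge_gap_s = 6,
       rank_window_s = 0.25,
       drift_uV = 100, drift_min_s = 10, jump_uV = 500)
}

#' Run the full interictal analysis on one recording
#'
#' Preprocesses the recording, detects active/stable phases per lead
#' from 6-s sliding-window full-band energy against the
#' preceding-hour baseline (clipped to the available history), tests
#' active vs stable window energies per lead (Wilcoxon rank-sum), and
#' ranks leads by interictal Sv DC fluctuation around the cross-lead
#' trend.
#'
#' @param rec an [recording()] object.
#' @param obs_span numeric `c(t0, t1)`: the observation span in
#'   seconds; the baseline is taken from the (up to) hour preceding
#'   `t0`.
#' @param params named list overriding the defaults (6-s windows,
#'   100% energy-increase criterion, 12-s minimum event, 6-s merge
#'   gap).
#' @return list of class `svdc_interictal_report`: `quality`,
#'   `excluded`, per-lead `phases` (list of `svdc_phases`), `tests`
#'   (data frame: lead, n_active windows, medians, p_value),
#'   `ranking` (lead fluctuation table), `baseline_clipped`, `params`.
#' @export
run_interictal_analysis <- function(rec, obs_span, params = list()) {
  p <- utils::modifyList(default_interictal_params(), params)
  if (length(obs_span) != 2L || obs_span[2] <= obs_span[1])
    stop("'obs_span' must be c(t0, t1) with t0 < t1")
  if (obs_span[1] <= 0)
    stop("observation span must start after t = 0 (a baseline period ",
         "must precede it)")
  pre <- preprocess_recording(rec, p, flag_until_s = obs_span[1])
  if (length(pre$excluded) == ncol(rec$samples))
    stop("all channels flagged as artifacts; nothing to analyze")
  clean <- pre$clean
  keep <- !(clean$labels %in% pre$excluded)
  labels <- clean$labels[keep]
  baseline_clipped <- obs_span[1] < 3600

  phases <- list()
  tests <- list()
  for (j in which(keep)) {
    x <- clean$samples[, j]
    base <- suppressWarnings(
      preceding_hour_baseline(x, clean$fs, obs_span[1],
                              window_s = p$window_s))
    idx <- sample_range(clean$fs, obs_span[1], obs_span[2], length(x))
    tr <- sliding_energy(x[idx], clean$fs, window_s = p$window_s,
                         t_start = obs_span[1])
    ph <- detect_active_phases(tr, base, increase = p$increase,
                               min_dur_s = p$min_dur_s,
                               merge_gap_s = p$merge_gap_s)
    lab <- clean$labels[j]
    phases[[lab]] <- ph
    cmp <- if (any(ph$active_mask) && any(!ph$active_mask))
      compare_phase_energy(tr$energy[!ph$active_mask],
                           tr$energy[ph$active_mask])
    else list(statistic = NA_real_, p_value = NA_real_,
              median_stable = stats::median(tr$energy),
              median_active = NA_real_, active_higher = FALSE,
              n_stable = sum(!ph$active_mask),
              n_active = sum(ph$active_mask))
    tests[[lab]] <- data.frame(
      lead = lab, baseline = base,
      n_active_windows = cmp$n_active, n_stable_windows = cmp$n_stable,
      median_stable = cmp$median_stable, median_active = cmp$median_active,
      active_higher = cmp$active_higher, p_value = cmp$p_value,
      stringsAsFactors = FALSE)
  }
  tests <- do.call(rbind, c(tests, list(make.row.names = FALSE)))

  svdc <- extract_svdc(pre$notched)
  obs_idx <- sample_range(clean$fs, obs_span[1], obs_span[2], nrow(svdc))
  ranking <- rank_leads_by_interictal_fluctuation(
    svdc[obs_idx, keep, drop = FALSE], clean$fs, labels = labels,
    window_s = p$rank_window_s)

  structure(list(obs_span = obs_span, quality = pre$quality,
                 excluded = pre$excluded, phases = phases,
                 tests = tests, ranking = ranking,
                 baseline_clipped = baseline_clipped, params = p),
            class = "svdc_interictal_report")
}
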