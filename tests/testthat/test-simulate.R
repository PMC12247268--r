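test_that("generation is deterministic and scales with the noise level", {
  shortsz <- list(onset_s = 5, duration_s = 20)   # unused, must fit
  cfg <- sim_config(n_electrodes = 2, contacts_per_electrode = 2,
                    duration_s = 30, seed = 5, seizure = shortsz)
  a <- generate_background(cfg)
  b <- generate_background(cfg)
  expect_identical(a$samples, b$samples)

  silent <- sim_config(n_electrodes = 2, contacts_per_electrode = 2,
                       duration_s = 30, seed = 5, seizure = shortsz,
                       noise = list(rms_uv = 0))
  expect_true(all(generate_background(silent)$samples == 0))
})

test_that("pink noise has the requested spectral slope", {
  set.seed(41)
  fs <- 1024
  x <- pink_noise(fs * 120, alpha = 1)
  # periodogram slope oracle: log-binned least squares over 0.1-100 Hz
  n <- length(x)
  p <- Mod(stats::fft(x))[2:(n %/% 2)]^2
  f <- (1:(n %/% 2 - 1)) * fs / n
  keep <- f >= 0.1 & f <= 100
  bins <- cut(log10(f[keep]), 40)
  lp <- tapply(log10(p[keep]), bins, mean)
  lf <- tapply(log10(f[keep]), bins, mean)
  slope <- stats::coef(stats::lm(lp ~ lf))[2]
  expect_equal(unname(slope), -1, tolerance = 0.2)
})

test_that("injected seizures carry construction-exact ground truth", {
  cfg <- compact_ictal_config(seed = 6, propagation = "pathway",
                              inter_lead_delay_s = 2)
  sim <- inject_seizure(generate_background(cfg), cfg)
  tr <- sim$truth$leads
  expect_true(all(tr$lf_onset_s - tr$dc_onset_s == 20))
  expect_true(all(tr$hf_onset_s == tr$lf_onset_s))
  ord <- lead_order(tr$lead)
  expect_equal(tr$lf_onset_s[ord] - 180, seq(0, by = 2, length.out = 6))
  expect_true(all(abs(tr$dc_shift_uv[tr$soz]) >=
                  max(abs(tr$dc_shift_uv[!tr$soz])) * 0.5))
  expect_equal(sim$truth$reconvergence_s, 180 + 90 + 20)
  ann <- sim$recording$annotations
  expect_true("seizure" %in% ann$label)

  vol <- compact_ictal_config(seed = 6, propagation = "volume")
  simv <- inject_seizure(generate_background(vol), vol)
  expect_equal(length(unique(simv$truth$leads$hf_onset_s)), 1L)
})

test_that("the pre-onset Sv DC ramp is invisible to the HF band", {
  cfg <- compact_ictal_config(seed = 7)
  bg <- generate_background(cfg)
  sim <- inject_seizure(bg, cfg)
  hf0 <- extract_band(bg, 40, 300)
  hf1 <- extract_band(sim$recording, 40, 300)
  # window between earliest DC onset and seizure onset
  idx <- (160 * cfg$fs):(180 * cfg$fs)
  e0 <- colSums(hf0[idx, ]^2)
  e1 <- colSums(hf1[idx, ]^2)
  expect_true(all(abs(e1 / e0 - 1) < 0.05))
})

test_that("interictal generation injects active phases and SOZ fluctuation", {
  cfg <- compact_interictal_config(
    seed = 8, active_intervals = list(c(300, 360), c(396, 420)))
  out <- generate_interictal(cfg)
  expect_equal(out$truth$active_intervals$t0, c(300, 396))
  expect_equal(out$truth$soz_leads, c("A1", "A2"))
  # energy inside an active interval ~4x the background level
  e_act <- segment_energy(out$recording$samples[, 3], cfg$fs, 310, 350)
  e_bg <- segment_energy(out$recording$samples[, 3], cfg$fs, 200, 240)
  expect_equal(e_act / e_bg, 4, tolerance = 1.5)

  expect_error(generate_interictal(compact_interictal_config(
    seed = 8, active_intervals = list(c(100, 200), c(150, 250)))),
    "overlap")
})

test_that("unit active gain leaves phases undetectable", {
  cfg <- compact_interictal_config(
    seed = 9, active_intervals = list(c(300, 360)), active_gain = 1)
  out <- generate_interictal(cfg)
  tr <- sliding_energy(out$recording$samples, cfg$fs, window_s = 6,
                       t_start = 0)
  base <- mean(tr$energy[tr$t1 <= 240])
  obs <- tr[tr$t0 >= 240, ]
  ph <- detect_active_phases(obs, base)
  # nothing resembling the injected interval is recovered
  jac <- interval_jaccard(ph$active, out$truth$active_intervals)
  expect_true(is.na(jac) || jac < 0.2)
})

test_that("a study regenerates byte-identical files from its manifest seeds", {
  base <- sim_config(n_electrodes = 2, contacts_per_electrode = 2,
                     duration_s = 300, seed = 1,
                     soz_leads = c("A1", "A2"),
                     seizure = list(onset_s = 180))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_study(d1, n_patients = 1, seizures_per_patient = 2,
                       base_config = base)
  m2 <- generate_study(d2, n_patients = 1, seizures_per_patient = 2,
                       base_config = base)
  expect_equal(nrow(m1), 2L)
  expect_identical(m1$seed, m2$seed)
  expect_identical(m1$propagation, c("pathway", "volume"))
  for (f in m1$file)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  rec <- read_edf(file.path(d1, m1$file[1]))
  expect_equal(rec$fs, base$fs)
  expect_equal(n_channels(rec), 4)
})

test_that("default ictal configuration lands in the Sv DC dominance regime", {
  # pooled across seizures, as the lead-fraction statistic is defined
  summaries <- list()
  for (sd in 1:3) {
    cfg <- sim_config(seed = sd)
    sim <- inject_seizure(generate_background(cfg), cfg)
    clean <- broadband_filter(notch_filter(sim$recording))
    bands <- decompose(clean)
    win <- ictal_window(cfg$seizure$onset_s,
                        record_duration_s = cfg$duration_s)
    summaries[[sd]] <- energy_ratio(bands, win[1], win[2])
  }
  pooled <- threshold_summary(summaries, thresholds = 0.6)
  expect_gte(pooled$fraction, 0.8)
})
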