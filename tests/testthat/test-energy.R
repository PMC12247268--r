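test_that("segment energy is the windowed sum of squares", {
  expect_equal(segment_energy(rep(2, 4), fs = 1, 0, 4), 16)
  expect_equal(segment_energy(rep(0, 100), fs = 10, 0, 10), 0)
  fs <- 100
  x <- sin(2 * pi * 2 * seq(0, 5 - 1 / fs, by = 1 / fs))
  expect_equal(segment_energy(x, fs, 0, 5), length(x) / 2,
               tolerance = 0.01)
  expect_error(segment_energy(1:10, 1, 5, 5), "t0 < t1")
})

test_that("energy over disjoint windows is additive", {
  set.seed(3)
  x <- rnorm(1000)
  fs <- 100
  parts <- sapply(seq(0, 8, by = 2), function(t0)
    segment_energy(x, fs, t0, t0 + 2))
  expect_equal(sum(parts), segment_energy(x, fs, 0, 10), tolerance = 1e-12)
})

test_that("the peri-ictal window spans 2 min either side and clips", {
  expect_equal(ictal_window(300), c(180, 420))
  expect_warning(w <- ictal_window(60, record_duration_s = 600),
                 "clipped")
  expect_equal(w, c(0, 180))
  expect_error(ictal_window(-5), "non-negative")
  expect_error(ictal_window(700, record_duration_s = 600), "outside")
})

test_that("energy ratios split a two-tone mixture by band power", {
  fs <- 1024
  dur <- 120
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  slow <- sin(2 * pi * 0.1 * t)
  fast <- sin(2 * pi * 100 * t)
  mk <- function(x) decompose(recording(matrix(x, ncol = 1), fs = fs,
                                        labels = "A1"))
  r_slow <- energy_ratio(mk(slow), 20, 100)
  expect_gte(r_slow$ratio_svdc, 0.95)
  r_fast <- energy_ratio(mk(fast), 20, 100)
  expect_lte(r_fast$ratio_svdc, 0.02)
  r_mix <- energy_ratio(mk(slow + fast), 20, 100)
  expect_equal(r_mix$ratio_svdc, 0.5, tolerance = 0.05)
})

test_that("zero-energy leads report missing ratios, not zero", {
  fs <- 1024
  bs <- decompose(recording(matrix(0, fs * 30, 2), fs = fs,
                            labels = c("A1", "A2")))
  r <- energy_ratio(bs, 0, 30)
  expect_true(all(is.na(r$ratio_svdc)))
  expect_equal(r$E_total, c(0, 0), ignore_attr = TRUE)
})

test_that("threshold summary counts and fractions behave", {
  ratios <- c(rep(0.95, 3), rep(0.7, 4), rep(0.3, 3))
  ts <- threshold_summary(ratios)
  expect_equal(ts$count, c(7L, 3L))
  expect_equal(ts$fraction, c(0.7, 0.3))
  # non-increasing in threshold
  ts2 <- threshold_summary(ratios, thresholds = seq(0.1, 0.9, by = 0.2))
  expect_true(all(diff(ts2$fraction) <= 0))
  # inclusive comparison
  expect_equal(threshold_summary(rep(0.6, 5))$count[1], 5L)
  expect_equal(threshold_summary(rep(1, 4), c(0.6, 0.9))$pct, c(100, 100))
  # missing ratios excluded but reported
  ts3 <- threshold_summary(c(0.7, NA, 0.5))
  expect_equal(ts3$n_leads, c(2L, 2L))
  expect_equal(attr(ts3, "n_missing"), 1L)
})

test_that("sliding energy windows sum squares and scale quadratically", {
  tr <- sliding_energy(rep(1, 600), fs = 10, window_s = 6)
  expect_true(all(tr$energy == 60))
  expect_equal(tr$t0[2] - tr$t0[1], 6)

  x <- rep(0, 600)
  x[250] <- 3
  tr2 <- sliding_energy(x, fs = 10, window_s = 6)
  hit <- tr2$energy > 0
  expect_equal(sum(hit), 1L)
  expect_equal(tr2$energy[hit], 9)

  set.seed(2)
  y <- rnorm(600)
  e1 <- sliding_energy(y, fs = 10, window_s = 6)$energy
  e2 <- sliding_energy(2 * y, fs = 10, window_s = 6)$energy
  expect_equal(e2, 4 * e1)
})

test_that("active phases follow the 100%-over-baseline rule", {
  mk_trace <- function(e) {
    n <- length(e)
    structure(data.frame(t0 = (seq_len(n) - 1) * 6, t1 = seq_len(n) * 6,
                         energy = e),
              window_s = 6, hop_s = 6)
  }
  flat <- mk_trace(rep(10, 50))
  ph <- detect_active_phases(flat, baseline = 10)
  expect_equal(nrow(ph$active), 0L)
  expect_equal(ph$stable$t1 - ph$stable$t0, 300)

  e <- rep(10, 50)
  e[21:25] <- 25                      # 30-s plateau at 2.5x baseline
  ph2 <- detect_active_phases(mk_trace(e), baseline = 10, min_dur_s = 12)
  expect_equal(nrow(ph2$active), 1L)
  expect_equal(ph2$active$t0, 120)
  expect_equal(ph2$active$t1, 150)

  # exactly 2.0x baseline everywhere: inclusive comparison, all active
  ph3 <- detect_active_phases(mk_trace(rep(20, 50)), baseline = 10)
  expect_equal(nrow(ph3$stable), 0L)
  expect_true(all(ph3$active_mask))

  expect_error(detect_active_phases(flat, baseline = 0), "positive")
})

test_that("interval Jaccard measures overlap of interval sets", {
  a <- data.frame(t0 = c(0, 10), t1 = c(5, 20))
  expect_equal(interval_jaccard(a, a), 1)
  b <- data.frame(t0 = 2.5, t1 = 5)
  expect_equal(interval_jaccard(data.frame(t0 = 0, t1 = 5), b), 0.5)
  expect_equal(interval_jaccard(a, data.frame(t0 = 30, t1 = 40)), 0)
})

test_that("preceding-hour baseline averages history and clips", {
  fs <- 10
  x <- rep(2, fs * 1200)
  b <- NULL
  expect_warning(b <- preceding_hour_baseline(x, fs, t_obs = 1200),
                 "less than 1 h")
  expect_equal(b, 4 * 6 * fs)          # 6-s windows of squared 2s
  expect_error(preceding_hour_baseline(x, fs, t_obs = 0), "history")
})

test_that("rank-sum comparison of phase energies is calibrated", {
  set.seed(8)
  a <- rexp(60)
  same <- compare_phase_energy(a, a)
  expect_gt(same$p_value, 0.9)

  stable <- rexp(50)
  active <- stable + 5
  cmp <- compare_phase_energy(stable, active)
  expect_lt(cmp$p_value, 0.001)
  expect_true(cmp$active_higher)

  # independent permutation oracle on the same samples: permute group
  # labels, recompute the rank-sum of the "active" group
  pooled <- c(stable, active)
  obs <- sum(rank(pooled)[51:100])
  set.seed(99)
  perm <- replicate(2000, {
    idx <- sample(100, 50)
    sum(rank(pooled)[idx])
  })
  p_perm <- mean(abs(perm - mean(perm)) >= abs(obs - mean(perm)))
  expect_lt(p_perm, 0.01)

  # swapping the samples flips the direction flag
  rev <- compare_phase_energy(active, stable)
  expect_false(rev$active_higher)
  expect_equal(rev$p_value, cmp$p_value)

  expect_warning(small <- compare_phase_energy(c(1, 2), c(3, 4, 5)),
                 "fewer than 3")
  expect_true(is.na(small$p_value))
})
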