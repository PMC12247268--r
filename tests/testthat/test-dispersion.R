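# Dispersion fixtures use small sampling rates: the statistics under
# test are per-window cross-lead spreads, independent of fs.

make_svdc <- function(mat, fs = 16) {
  colnames(mat) <- paste0("A", seq_len(ncol(mat)))
  mat
}

test_that("identical leads have zero dispersion", {
  fs <- 16
  x <- sin(2 * pi * 0.1 * seq(0, 120, by = 1 / fs))
  m <- make_svdc(cbind(x, x, x), fs)
  d <- svdc_dispersion(m, fs, ref_interval = c(0, 30))
  expect_true(all(d$values < 1e-12))
})

test_that("two leads at constant offsets +/-d give dispersion d", {
  fs <- 16
  n <- 120 * fs
  m <- make_svdc(cbind(rep(0, n), rep(0, n)), fs)
  m[(60 * fs):n, 1] <- 5
  m[(60 * fs):n, 2] <- -5
  d <- svdc_dispersion(m, fs, ref_interval = c(0, 30))
  late <- d$values[d$times > 70]
  expect_equal(unique(round(late, 10)), 5)
})

test_that("dispersion equals a brute-force cross-lead SD oracle", {
  fs <- 16
  set.seed(21)
  m <- make_svdc(matrix(rnorm(120 * fs * 5), ncol = 5), fs)
  d <- svdc_dispersion(m, fs, ref_interval = c(0, 20), window_s = 2)
  # oracle: reference, window-average, then population SD per window
  ref_mean <- colMeans(m[1:(20 * fs), ])
  w <- 2 * fs
  oracle <- sapply(seq_len(nrow(m) %/% w), function(i) {
    rows <- ((i - 1) * w + 1):(i * w)
    v <- colMeans(m[rows, , drop = FALSE]) - ref_mean
    sqrt(mean((v - mean(v))^2))
  })
  expect_equal(d$values, oracle, tolerance = 1e-12)
})

test_that("dispersion ignores common shifts and scales with gain", {
  fs <- 16
  set.seed(22)
  n <- 120 * fs
  m <- make_svdc(matrix(rnorm(n * 4), ncol = 4), fs)
  common <- 50 * sin(2 * pi * 0.05 * seq_len(n) / fs) + 20
  d0 <- svdc_dispersion(m, fs, c(0, 20))
  d1 <- svdc_dispersion(m + common, fs, c(0, 20))
  expect_equal(d1$values, d0$values, tolerance = 1e-10)
  d3 <- svdc_dispersion(m * 3, fs, c(0, 20))
  expect_equal(d3$values, 3 * d0$values, tolerance = 1e-10)
})

test_that("dispersion onset detection follows the sustained-run rule", {
  fs <- 16
  n <- 300 * fs
  set.seed(23)
  base <- matrix(rnorm(n * 3), ncol = 3)

  flat <- make_svdc(base, fs)
  d <- svdc_dispersion(flat, fs, c(0, 60))
  ev <- detect_dispersion_onset(d, k = 3, min_dur_s = 10)
  expect_true(is.na(ev$onset_s))

  # step: leads pull apart strongly at t = 100 for 60 s
  stepped <- base
  stepped[(100 * fs):(160 * fs), 1] <- stepped[(100 * fs):(160 * fs), 1] + 30
  stepped[(100 * fs):(160 * fs), 2] <- stepped[(100 * fs):(160 * fs), 2] - 30
  d2 <- svdc_dispersion(make_svdc(stepped, fs), fs, c(0, 60))
  ev2 <- detect_dispersion_onset(d2, k = 3, min_dur_s = 10)
  expect_equal(ev2$onset_s, 100, tolerance = 2)
  expect_false(is.na(ev2$reconvergence_s))

  # a 5-s excursion is shorter than the 10-s sustained requirement
  spiky <- base
  spiky[(100 * fs):(105 * fs), 1] <- spiky[(100 * fs):(105 * fs), 1] + 30
  d3 <- svdc_dispersion(make_svdc(spiky, fs), fs, c(0, 60))
  ev3 <- detect_dispersion_onset(d3, k = 3, min_dur_s = 10)
  expect_true(is.na(ev3$onset_s))

  expect_error(svdc_dispersion(make_svdc(base[, 1, drop = FALSE], fs),
                               fs, c(0, 60)), "2 unflagged leads")
})

test_that("band onset detection is scale-robust and duration-gated", {
  fs <- 256
  n <- 300 * fs
  set.seed(24)
  noise <- matrix(rnorm(n * 2), ncol = 2)
  expect_true(is.na(detect_band_onset(noise, fs, ref_interval = c(0, 60))))

  burst <- noise
  idx <- (200 * fs):(240 * fs)
  burst[idx, ] <- burst[idx, ] + 8 * matrix(rnorm(length(idx) * 2), ncol = 2)
  on1 <- detect_band_onset(burst, fs, ref_interval = c(0, 60))
  expect_equal(on1, 200, tolerance = 2)
  on2 <- detect_band_onset(2 * burst, fs, ref_interval = c(0, 60))
  expect_equal(on2, on1)
})

test_that("onset ordering reports pairwise latencies and precedence", {
  o <- onset_ordering(100, 130, 125)
  expect_equal(o$latency_svdc_to_lf, 30)
  expect_equal(o$latency_svdc_to_hf, 25)
  expect_true(o$svdc_first)

  o2 <- onset_ordering(NA, 130, 125)
  expect_true(is.na(o2$latency_svdc_to_lf))
  expect_false(o2$svdc_first)

  o3 <- onset_ordering(100, NA, 90)
  expect_false(o3$svdc_first)
  expect_error(onset_ordering(NA, NA, NA), "at least one onset")
})

test_that("lead ranking scores residual fluctuation around the trend", {
  fs <- 16
  n <- 660 * fs
  trend <- 20 * sin(2 * pi * 0.02 * seq_len(n) / fs)
  set.seed(25)
  resid <- matrix(rnorm(n * 5, sd = 2), ncol = 5)
  resid[, 3] <- resid[, 3] * 5
  m <- trend + resid
  colnames(m) <- paste0("A", 1:5)
  rk <- rank_leads_by_interictal_fluctuation(m, fs)
  expect_equal(rk$lead[1], "A3")
  expect_true(all(sort(rk$rank) == 1:5))

  # exchangeable leads: scores within a modest spread of each other
  rk2 <- rank_leads_by_interictal_fluctuation(trend +
    matrix(rnorm(n * 4, sd = 2), ncol = 4, dimnames = list(NULL, paste0("B", 1:4))), fs)
  expect_lt(diff(range(rk2$score)) / mean(rk2$score), 0.2)

  expect_error(rank_leads_by_interictal_fluctuation(m[, 1:2], fs),
               "at least 3 leads")
  expect_warning(rank_leads_by_interictal_fluctuation(m[1:(60 * fs), ], fs),
                 "shorter")
})
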