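test_that("autocorrelation is 1 at zero lag and -1 at half period", {
  set.seed(31)
  s <- rnorm(500)
  expect_identical(autocorrelation(s, 0, fs = 100), 1)
  # full-energy normalization as written: the overlap shortfall is
  # lag/n, so a long record is needed for the half-period value ~ -1
  fs <- 1000
  sine <- sin(2 * pi * 5 * seq(0, 20 - 1 / fs, by = 1 / fs))
  expect_equal(autocorrelation(sine, 0.1, fs), -1, tolerance = 0.01)
  expect_warning(expect_true(is.na(autocorrelation(rep(0, 100), 0.1, 100))),
                 "zero-energy")
  expect_error(autocorrelation(1:10, 2, fs = 10), "record length")
})

test_that("auto/cross-correlation match naive-summation oracles", {
  set.seed(32)
  for (i in 1:10) {
    s <- rnorm(1000)
    lag <- sample(0:500, 1)
    expect_equal(autocorrelation(s, lag / 100, fs = 100),
                 naive_autocorr(s, lag), tolerance = 1e-10)
    s2 <- rnorm(1000)
    expect_equal(cross_correlation(s, s2), naive_crosscorr(s, s2),
                 tolerance = 1e-10)
    # and against the standard Pearson implementation
    expect_equal(cross_correlation(s, s2), stats::cor(s, s2),
                 tolerance = 1e-12)
  }
})

test_that("cross-correlation handles affine transforms and degenerate input", {
  set.seed(33)
  s <- rnorm(200)
  expect_equal(cross_correlation(s, s), 1)
  expect_equal(cross_correlation(s, -3 * s + 7), -1)
  expect_equal(cross_correlation(s, 2 * s + 1), 1)
  expect_warning(expect_true(is.na(cross_correlation(s, rep(4, 200)))),
                 "constant")
  expect_error(cross_correlation(s, rnorm(100)), "equal length")
})

test_that("staged cross-correlation splits the span into thirds", {
  set.seed(34)
  fs <- 100
  s <- rnorm(60 * fs)
  st <- staged_cross_correlation(s, s, fs, span = c(10, 40))
  expect_equal(st$t0, c(10, 20, 30))
  expect_equal(st$rho, rep(1, 3), tolerance = 1e-12)

  for (i in 1:5) {
    a <- rnorm(60 * fs)
    b <- rnorm(60 * fs)
    stn <- staged_cross_correlation(a, b, fs, span = c(0, 60))
    expect_true(all(abs(stn$rho) < 0.2))
  }
})

test_that("instantaneous phase advances at the tone frequency", {
  fs <- 200
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  ph <- instantaneous_phase(cos(2 * pi * 4 * t))
  unw <- ph + 2 * pi * cumsum(c(0, diff(ph) < -pi))
  core <- seq.int(fs, length(t) - fs)
  slope <- stats::coef(stats::lm(unw[core] ~ t[core]))[2]
  expect_equal(unname(slope), 2 * pi * 4, tolerance = 0.01)

  dphi <- instantaneous_phase(cos(2 * pi * 4 * t)) -
    instantaneous_phase(sin(2 * pi * 4 * t))
  dphi <- atan2(sin(dphi), cos(dphi))
  expect_equal(mean(dphi[core]), pi / 2, tolerance = 0.05)

  x <- cos(2 * pi * 4 * t)
  flip <- instantaneous_phase(-x) - instantaneous_phase(x)
  flip <- atan2(sin(flip), cos(flip))   # each wraps to +pi or -pi
  expect_equal(mean(abs(flip[core])), pi, tolerance = 0.01)

  expect_error(instantaneous_phase(rep(0, 100)), "zero signal")
})

test_that("PLV is 1 for locked phases and ~N^(-1/2) for random ones", {
  fs <- 200
  ph <- instantaneous_phase(cos(2 * pi * 4 * seq(0, 5, by = 1 / fs)))
  expect_equal(plv(ph, ph), 1, tolerance = 1e-15)
  expect_equal(plv(ph, ph + 1.2), 1, tolerance = 1e-12)
  set.seed(35)
  u1 <- runif(10000, -pi, pi)
  u2 <- runif(10000, -pi, pi)
  expect_lte(plv(u1, u2), 0.05)
  expect_error(plv(u1, u2[1:10]), "equal length")
})

test_that("PLV bounds and common-phase invariance hold", {
  set.seed(36)
  for (i in 1:20) {
    n <- sample(10:500, 1)
    p1 <- runif(n, -pi, pi)
    p2 <- runif(n, -pi, pi)
    v <- plv(p1, p2)
    expect_gte(v, 0)
    expect_lte(v, 1)
    expect_equal(plv(p1 + 0.7, p2 + 0.7), v, tolerance = 1e-12)
  }
})

test_that("PLV matrices are symmetric with unit diagonal", {
  fs <- 256
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 60 * t) + 0.1 * rnorm(length(t))
  dup <- cbind(A1 = x, A2 = x, A3 = x)
  pm <- plv_matrix(dup)
  expect_true(all(abs(pm$values - 1) < 1e-10))

  set.seed(37)
  noise <- matrix(rnorm(length(t) * 4), ncol = 4,
                  dimnames = list(NULL, paste0("B", 1:4)))
  pm2 <- plv_matrix(noise)
  expect_identical(pm2$values, t(pm2$values))
  expect_true(all(diag(pm2$values) == 1))
  off <- pm2$values[upper.tri(pm2$values)]
  expect_true(all(off <= 0.1))
})

test_that("staged PLV summarizes per-stage synchronization", {
  fs <- 256
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 50 * t)
  ident <- cbind(A1 = x, A2 = x, A3 = x)
  attr(ident, "fs") <- fs
  sp <- staged_plv(ident, span = c(0, 30))
  expect_equal(sp$stages$mean_plv, rep(1, 3), tolerance = 1e-10)

  set.seed(38)
  noise <- matrix(rnorm(length(t) * 3), ncol = 3,
                  dimnames = list(NULL, paste0("C", 1:3)))
  attr(noise, "fs") <- fs
  spn <- staged_plv(noise, span = c(0, 30))
  expect_true(all(spn$stages$mean_plv <= 0.2))
})
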