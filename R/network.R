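# Correlation and phase-synchronization propagation analysis:
# normalized autocorrelation, mean-centered cross-correlation, staged
# (thirds-of-seizure) correlation, analytic-signal instantaneous phase,
# and the phase-locking value (PLV) network.

#' Normalized autocorrelation at a lag
#'
#' Discrete-sum autocorrelation over the overlapping support,
#' normalized by the full-signal energy, so the value at lag 0 is
#' exactly 1.
#'
#' @param s numeric signal vector.
#' @param tau_s lag in seconds (may be negative).
#' @param fs sampling rate in Hz.
#' @return the autocorrelation value (`NA` with a warning for a
#'   zero-energy signal).
#' @export
autocorrelation <- function(s, tau_s, fs) {
  lag <- as.integer(round(abs(tau_s) * fs))
  n <- length(s)
  if (lag >= n) stop("|tau_s| must be smaller than the record length")
  denom <- sum(s^2)
  if (denom == 0) {
    warning("zero-energy signal; autocorrelation undefined")
    return(NA_real_)
  }
  if (lag == 0L) return(1)
  sum(s[seq_len(n - lag)] * s[seq.int(lag + 1L, n)]) / denom
}

#' Mean-centered cross-correlation coefficient
#'
#' Centered, normalized correlation between two equal-length signals,
#' in `[-1, 1]`.
#'
#' @param s1,s2 numeric vectors of equal length (>= 2).
#' @return the correlation coefficient (`NA` with a warning when
#'   either signal is constant).
#' @export
cross_correlation <- function(s1, s2) {
  if (length(s1) != length(s2)) stop("signals must have equal length")
  if (length(s1) < 2L) stop("signals must have length >= 2")
  d1 <- s1 - mean(s1)
  d2 <- s2 - mean(s2)
  denom <- sqrt(sum(d1^2)) * sqrt(sum(d2^2))
  if (denom == 0) {
    warning("constant signal; cross-correlation undefined")
    return(NA_real_)
  }
  sum(d1 * d2) / denom
}

stage_bounds <- function(span, n_stages, boundaries = NULL) {
  if (!is.null(boundaries)) {
    edges <- sort(unique(c(span[1], boundaries, span[2])))
  } else {
    edges <- seq(span[1], span[2], length.out = n_stages + 1L)
  }
  data.frame(stage = seq_len(length(edges) - 1L),
             t0 = edges[-length(edges)], t1 = edges[-1L])
}

#' Cross-correlation over seizure stages
#'
#' Splits the seizure span into `n_stages` equal stages (default
#' thirds) and computes the cross-correlation coefficient in each.
#'
#' @param s1,s2 numeric vectors covering the same record, aligned at
#'   `t = 0`.
#' @param fs sampling rate in Hz.
#' @param span numeric `c(t0, t1)`: the seizure span in seconds.
#' @param n_stages number of equal stages (default 3).
#' @param boundaries optional explicit interior stage boundaries in
#'   seconds, overriding `n_stages`.
#' @return a data frame with columns `stage`, `t0`, `t1`, `rho`.
#' @export
staged_cross_correlation <- function(s1, s2, fs, span, n_stages = 3,
                                     boundaries = NULL) {
  if (length(s1) != length(s2)) stop("signals must have equal length")
  st <- stage_bounds(span, n_stages, boundaries)
  st$rho <- vapply(seq_len(nrow(st)), function(i) {
    idx <- sample_range(fs, st$t0[i], st$t1[i], length(s1))
    if (length(idx) < 2L) stop("stage ", i, " shorter than 2 samples")
    cross_correlation(s1[idx], s2[idx])
  }, numeric(1))
  st
}

# Analytic signal via the FFT half-spectrum construction (no installed
# package provides a Hilbert transform).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a band-limited signal
#'
#' Phase of the analytic signal (quadrature construction via the FFT),
#' in radians wrapped to `(-pi, pi]`. The input should already be
#' band-limited (e.g. one column of a bandset component).
#'
#' @param x numeric vector.
#' @return numeric vector of phases.
#' @export
instantaneous_phase <- function(x) {
  if (all(x == 0)) stop("zero signal has no defined phase")
  Arg(analytic_signal(x))
}

#' Phase-locking value of two phase series
#'
#' Modulus of the mean unit phasor of the phase differences:
#' `PLV = |mean(exp(i * (phi1 - phi2)))|`, in `[0, 1]`. Identical (or
#' constant-offset) phase series give exactly 1; independent phases
#' give values near `1/sqrt(N)`.
#'
#' @param phase1,phase2 numeric phase series in radians, equal length.
#' @return the PLV.
#' @export
plv <- function(phase1, phase2) {
  if (length(phase1) != length(phase2))
    stop("phase series must have equal length")
  if (!length(phase1)) stop("phase series must be non-empty")
  Mod(mean(exp(1i * (phase1 - phase2))))
}

#' Pairwise PLV matrix over a window
#'
#' Computes instantaneous phases of the selected band component for
#' every lead over the window, then all pairwise PLVs.
#'
#' @param bands an `svdc_bandset` from [decompose()], or a numeric
#'   matrix of band-limited series (one column per lead).
#' @param band which component to use when `bands` is a bandset:
#'   `"hf"` (default), `"lf"` or `"svdc"`.
#' @param window numeric `c(t0, t1)` in seconds, or `NULL` for the
#'   whole record.
#' @param exclude lead labels to drop.
#' @param labels lead labels (default from the bandset or column
#'   names).
#' @return an object of class `svdc_plv_matrix`: list with `labels`,
#'   `values` (symmetric matrix, unit diagonal), `band`, `window`.
#' @export
plv_matrix <- function(bands, band = c("hf", "lf", "svdc"),
                       window = NULL, exclude = character(),
                       labels = NULL) {
  band <- match.arg(band)
  if (inherits(bands, "svdc_bandset")) {
    m <- bands[[band]]
    fs <- bands$fs
    if (is.null(labels)) labels <- bands$labels
  } else {
    m <- as.matrix(bands)
    fs <- attr(bands, "fs")
    if (is.null(labels)) labels <- colnames(m)
  }
  if (is.null(labels)) labels <- paste0("CH", seq_len(ncol(m)))
  keep <- !(labels %in% exclude)
  m <- m[, keep, drop = FALSE]
  labels <- labels[keep]
  if (ncol(m) < 2L) stop("PLV matrix needs at least 2 leads")
  if (!is.null(window)) {
    if (is.null(fs)) stop("windowing needs a sampling rate")
    idx <- sample_range(fs, window[1], window[2], nrow(m))
    m <- m[idx, , drop = FALSE]
  }
  # unit phasors per lead; PLV(i,j) = |mean(z_i * conj(z_j))|
  Z <- apply(m, 2, function(col) exp(1i * instantaneous_phase(col)))
  vals <- Mod(Conj(t(Z)) %*% Z) / nrow(Z)
  diag(vals) <- 1
  dimnames(vals) <- list(labels, labels)
  structure(list(labels = labels, values = vals, band = band,
                 window = window),
            class = "svdc_plv_matrix")
}

#' @export
print.svdc_plv_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("<svdc_plv_matrix> %d leads, band %s; mean off-diagonal PLV %.3f\n",
              length(x$labels), x$band, mean(off)))
  invisible(x)
}

mean_offdiag <- function(m) mean(m[upper.tri(m)])

#' Per-stage PLV matrices across a seizure
#'
#' Splits the seizure span into stages and computes the PLV matrix in
#' each, plus the scalar summary (mean off-diagonal PLV) per stage.
#'
#' @inheritParams plv_matrix
#' @param span numeric `c(t0, t1)`: the seizure span in seconds.
#' @param n_stages number of equal stages (default 3).
#' @param boundaries optional explicit interior boundaries.
#' @return list with `stages` (data frame `stage`, `t0`, `t1`,
#'   `mean_plv`) and `matrices` (list of `svdc_plv_matrix`).
#' @export
staged_plv <- function(bands, span, n_stages = 3, boundaries = NULL,
                       band = c("hf", "lf", "svdc"),
                       exclude = character()) {
  band <- match.arg(band)
  st <- stage_bounds(span, n_stages, boundaries)
  mats <- lapply(seq_len(nrow(st)), function(i)
    plv_matrix(bands, band = band, window = c(st$t0[i], st$t1[i]),
               exclude = exclude))
  st$mean_plv <- vapply(mats, function(m) mean_offdiag(m$values),
                        numeric(1))
  list(stages = st, matrices = mats)
}
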