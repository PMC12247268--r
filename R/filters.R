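# IIR filter plumbing shared by the preprocessing and band-decomposition
# steps. Every filter in this package is applied zero-phase
# (forward-backward), so onset latencies downstream are never biased by
# group delay; the price is that the effective order doubles and the
# gain at the design cutoff is 1/2 instead of 1/sqrt(2).
#
# Butterworth designs are realized as cascaded second-order sections
# computed from the closed-form analog poles via the bilinear
# transform: at fs = 1024 Hz a 0.01 Hz band edge puts poles so close
# to z = 1 that the expanded polynomial (b, a) form is numerically
# unstable on long records, while the biquad cascade is well behaved.

# Odd (point-symmetric) reflection padding, as in the classic filtfilt
# edge treatment: continues the signal through its end points so a
# nonzero offset does not excite a start-up transient.
reflect_pad <- function(x, pad) {
  n <- length(x)
  pad <- min(as.integer(pad), n - 1L)
  if (pad <= 0L) return(list(x = x, pad = 0L))
  head_ref <- 2 * x[1] - x[seq.int(pad + 1L, 2L)]
  tail_ref <- 2 * x[n] - x[seq.int(n - 1L, n - pad)]
  list(x = c(head_ref, x, tail_ref), pad = pad)
}

# One direct-form section: the short MA part is vectorized, the AR
# part runs through the C recursion in stats::filter. Identical output
# to signal::filter for the same (b, a), without its ts bookkeeping.
section_forward <- function(x, b, a) {
  n <- length(x)
  v <- b[1] * x
  if (length(b) > 1L && n > 1L)
    v[-1L] <- v[-1L] + b[2] * x[-n]
  if (length(b) > 2L && n > 2L)
    v[-(1:2)] <- v[-(1:2)] + b[3] * x[seq_len(n - 2L)]
  if (length(a) > 1L)
    v <- stats::filter(v, -a[-1L], method = "recursive")
  as.numeric(v)
}

apply_forward <- function(x, filt) {
  if (inherits(filt, "svdc_sos")) {
    for (sec in filt$sections) x <- section_forward(x, sec$b, sec$a)
    x
  } else if (length(filt$b) <= 3L && length(filt$a) <= 3L) {
    section_forward(x, filt$b, filt$a)
  } else {
    as.numeric(signal::filter(filt, x))
  }
}

# Zero-phase application of a filter (single ARMA or biquad cascade)
# with reflection padding. `pad` is in samples; callers size it to the
# filter's settling length.
zero_phase_filter <- function(x, filt, pad = 0L) {
  p <- reflect_pad(x, pad)
  y <- apply_forward(p$x, filt)
  y <- rev(apply_forward(rev(y), filt))
  if (p$pad > 0L) y <- y[seq.int(p$pad + 1L, p$pad + length(x))]
  y
}

# Apply a filter to every channel of a matrix (or vector).
filter_channels <- function(samples, filt, pad = 0L) {
  if (is.matrix(samples)) {
    out <- samples
    for (j in seq_len(ncol(samples)))
      out[, j] <- zero_phase_filter(samples[, j], filt, pad)
    out
  } else {
    zero_phase_filter(samples, filt, pad)
  }
}

# --- Butterworth second-order-section design ------------------------

# Analog Butterworth prototype poles (unit cutoff, left half-plane).
butter_proto_poles <- function(order) {
  k <- seq_len(order)
  exp(1i * pi * (2 * k + order - 1) / (2 * order))
}

bilinear_z <- function(s, fs2) (1 + s / fs2) / (1 - s / fs2)

# Pair a pole multiset into conjugate (or real) pairs.
pair_poles <- function(poles) {
  pairs <- list()
  cplx <- poles[Im(poles) > 1e-9]
  realp <- Re(poles[abs(Im(poles)) <= 1e-9])
  for (p in cplx) pairs[[length(pairs) + 1L]] <- c(p, Conj(p))
  if (length(realp)) {
    realp <- sort(realp)
    i <- 1L
    while (i + 1L <= length(realp)) {
      pairs[[length(pairs) + 1L]] <- complex(real = realp[c(i, i + 1L)])
      i <- i + 2L
    }
    if (i == length(realp))
      pairs[[length(pairs) + 1L]] <- complex(real = realp[i])
  }
  pairs
}

# Build one digital section from z-plane poles (length 1 or 2) and an
# equal number of z-plane zeros; unit-normalized at z0 (a point on the
# unit circle chosen in the passband).
make_section <- function(zpoles, zzeros, z0) {
  a <- Re(c(1, -sum(zpoles), if (length(zpoles) == 2L) prod(zpoles) else NULL))
  b <- Re(c(1, -sum(zzeros), if (length(zzeros) == 2L) prod(zzeros) else NULL))
  g <- abs(sum(a * z0^-(seq_along(a) - 1)) /
           sum(b * z0^-(seq_along(b) - 1)))
  signal::Arma(b = b * g, a = a)
}

# Butterworth design as a biquad cascade. type: "low", "high", "pass";
# edges_hz of length 1 (low/high) or 2 (pass).
design_butter <- function(order, edges_hz, fs, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  nyq <- fs / 2
  if (any(edges_hz <= 0) || any(edges_hz >= nyq))
    stop("filter edge(s) ", paste(edges_hz, collapse = "-"),
         " Hz must lie strictly inside (0, ", nyq, ") Hz")
  fs2 <- 2 * fs
  W <- fs2 * tan(pi * edges_hz / fs)     # prewarped analog edges
  p <- butter_proto_poles(order)
  if (type == "low") {
    spoles <- W[1] * p
    zero_per_sec <- function(k) rep(-1 + 0i, k)   # zeros at z = -1
    z0 <- 1 + 0i                                  # unity at DC
  } else if (type == "high") {
    spoles <- W[1] / p
    zero_per_sec <- function(k) rep(1 + 0i, k)    # zeros at z = +1
    z0 <- -1 + 0i                                 # unity at Nyquist
  } else {
    if (length(edges_hz) != 2L || edges_hz[1] >= edges_hz[2])
      stop("band-pass needs edges c(low, high) with low < high")
    B <- W[2] - W[1]
    W0 <- sqrt(W[1] * W[2])
    spoles <- unlist(lapply(p, function(pk) {
      disc <- sqrt((B * pk)^2 / 4 - W0^2 + 0i)
      c(B * pk / 2 + disc, B * pk / 2 - disc)
    }))
    zero_per_sec <- function(k) c(1 + 0i, -1 + 0i)[seq_len(k)]
    f0 <- atan(W0 / fs2) * fs / pi     # digital image of the analog center
    z0 <- exp(1i * 2 * pi * f0 / fs)              # unity at center
  }
  zpoles <- bilinear_z(spoles, fs2)
  sections <- lapply(pair_poles(zpoles), function(pp)
    make_section(pp, zero_per_sec(length(pp)), z0))
  structure(list(sections = sections, fs = fs, type = type,
                 edges_hz = edges_hz, order = order),
            class = "svdc_sos")
}

# Reflection pad sized to the settling length of the slowest edge:
# roughly three periods of the lowest edge frequency, capped so very
# low high-pass edges do not triple the work on long records.
settling_pad <- function(fs, low_edge_hz, n, cap_s = 60) {
  pad_s <- min(3 / low_edge_hz, cap_s)
  min(as.integer(round(pad_s * fs)), n - 1L)
}

# RBJ biquad notch; the signal package ships no notch designer.
design_notch <- function(freq_hz, fs, quality_factor = 30) {
  if (freq_hz >= fs / 2)
    stop("notch frequency ", freq_hz, " Hz is at or above Nyquist (",
         fs / 2, " Hz)")
  w0 <- 2 * pi * freq_hz / fs
  alpha <- sin(w0) / (2 * quality_factor)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  signal::Arma(b = b, a = a)
}

#' Magnitude response of a designed filter
#'
#' Evaluates the transfer function of a digital filter on the unit
#' circle at the requested frequencies. With `zero_phase = TRUE` the
#' squared magnitude is returned, which is the effective gain of the
#' forward-backward application used throughout this package. This is
#' the measurement used as the independent oracle for filter-contract
#' tests.
#'
#' @param filt a filter as used internally: either an `Arma` object
#'   (e.g. from [signal::butter()]) or the biquad-cascade objects this
#'   package designs.
#' @param freq_hz numeric vector of frequencies in Hz.
#' @param fs sampling rate in Hz.
#' @param zero_phase if `TRUE` (default) return the squared magnitude,
#'   i.e. the gain after forward-backward filtering.
#' @return numeric vector of gains, same length as `freq_hz`.
#' @export
filter_response <- function(filt, freq_hz, fs, zero_phase = TRUE) {
  w <- 2 * pi * freq_hz / fs
  eval_poly <- function(coef, w) {
    k <- seq_along(coef) - 1
    vapply(w, function(wi) sum(coef * exp(-1i * wi * k)), complex(1))
  }
  one_mag <- function(b, a) Mod(eval_poly(b, w) / eval_poly(a, w))
  h <- if (inherits(filt, "svdc_sos")) {
    Reduce(`*`, lapply(filt$sections, function(s) one_mag(s$b, s$a)))
  } else {
    one_mag(filt$b, filt$a)
  }
  if (zero_phase) h^2 else h
}
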