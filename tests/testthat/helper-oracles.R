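# Naive-summation oracles for the normalized auto- and
# cross-correlation, written as explicit loops so they stay independent
# of the vectorized implementations they check.

naive_autocorr <- function(s, lag) {
  n <- length(s)
  num <- 0
  for (i in seq_len(n - lag)) num <- num + s[i] * s[i + lag]
  den <- 0
  for (i in seq_len(n)) den <- den + s[i]^2
  num / den
}

naive_crosscorr <- function(s1, s2) {
  m1 <- sum(s1) / length(s1)
  m2 <- sum(s2) / length(s2)
  num <- 0; d1 <- 0; d2 <- 0
  for (i in seq_along(s1)) {
    num <- num + (s1[i] - m1) * (s2[i] - m2)
    d1 <- d1 + (s1[i] - m1)^2
    d2 <- d2 + (s2[i] - m2)^2
  }
  num / sqrt(d1 * d2)
}
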