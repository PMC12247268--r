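# Shared fixtures: tone recordings and compact simulation configs used
# across the module tests. All fixtures are built in code at test time.

tone_rec <- function(freq_hz, fs, duration_s, amp = 1, n_ch = 1,
                     labels = NULL) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  x <- amp * sin(2 * pi * freq_hz * t)
  recording(matrix(rep(x, n_ch), ncol = n_ch), fs = fs, labels = labels)
}

rms <- function(x) sqrt(mean(x^2))

# steady-state interior of a series (drop a fraction at both ends)
interior <- function(x, frac = 0.2) {
  n <- length(x)
  x[seq.int(floor(n * frac) + 1L, ceiling(n * (1 - frac)))]
}

# Compact ictal simulation: 6 leads, 5 min, onset at 180 s. Small
# montage keeps multi-seed pipeline studies fast while preserving the
# full seizure structure (SOZ electrode + a second shaft).
compact_ictal_config <- function(seed, propagation = "pathway", ...) {
  sim_config(n_electrodes = 2, contacts_per_electrode = 3,
             duration_s = 300, seed = seed,
             soz_leads = c("A1", "A2"),
             seizure = utils::modifyList(
               list(onset_s = 180, propagation = propagation,
                    common_mix_max = NULL),
               list(...)))
}

compact_ictal_params <- list(pre_s = 60, post_s = 60)

# Compact interictal simulation: 6 leads, 8 min, observation span in
# the second half so the first half serves as (clipped) baseline.
compact_interictal_config <- function(seed, active_intervals = list(),
                                      ...) {
  sim_config(n_electrodes = 2, contacts_per_electrode = 3,
             duration_s = 480, seed = seed,
             soz_leads = c("A1", "A2"),
             interictal = utils::modifyList(
               list(active_intervals = active_intervals),
               list(...)))
}
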