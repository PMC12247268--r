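---
title: "Analyzing the slow-varying DC field of intracranial EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing the slow-varying DC field of intracranial EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(svdcfield)
```

## The problem and the quantity of interest

Stereo-EEG (SEEG) practice reads seizures mostly in the rhythmic bands:
low-voltage fast activity (LVFA, 40–300 Hz) marks electrographic
onset, and 0.5–40 Hz rhythms carry the visible ictal discharge. Below
all of that sits the infraslow component — 0.01–0.5 Hz, here called
the *slow-varying DC field* (Sv DC) — which standard review filters
discard. This package implements a complete analysis of that
component on multichannel intracranial recordings:

* **Band decomposition.** The Sv DC is defined by a second-order
  Butterworth low-pass at 0.5 Hz; LF (0.5–40 Hz) and HF (40–300 Hz)
  by 4th-order Butterworth band-passes. An equivalent piecewise
  definition — the mean over consecutive 2-s windows, held constant
  within each window — is provided (`piecewise_dc()`), and on
  slow-dominated signals the two track each other closely (tested as
  a correlation bound, not an identity).
* **Energy dominance.** For a window \([t_0, t_1)\) the band energy is
  the plain sum of squared samples, and the Sv DC *energy ratio* is
  \(E_{svdc}/E_{total}\), with the denominator taken from the full
  preprocessed (0.01–300 Hz) signal. `threshold_summary()` pools
  ratios across leads and recordings and reports the fraction of
  leads at or above thresholds (inclusive \(\ge\), defaults 60% and
  90%), printing both numerator and denominator.
* **Dispersion.** Leads are referenced to their mean over a pre-ictal
  reference interval; the dispersion trace is the cross-lead
  *population* SD (MAD optional) of the per-2-s-window mean Sv DC.
  A common shift of the whole field leaves it unchanged; leads
  pulling apart raise it. Onset is the earliest sustained
  (\(\ge\) 10 s) excursion above median + 3 MAD of the reference
  interval; the peak and the first sustained return below threshold
  (re-convergence) are reported alongside.
* **Interictal phases.** Six-second sliding-window energy is compared
  against the mean window energy of the (up to one) preceding hour;
  windows at or above twice the baseline (a 100% increase) form
  *active* phases, the complement is *stable*, and the two samples of
  window energies are compared with a two-sided Wilcoxon rank-sum
  test. Leads are ranked by the SD of their Sv DC residual around the
  cross-lead median trend; leads inside the epileptogenic zone
  fluctuate more.
* **Propagation.** Normalized autocorrelation and mean-centered
  cross-correlation (the latter identical to Pearson correlation) are
  computed per seizure stage (equal thirds of the seizure span by
  default), and phase-locking values
  \(\mathrm{PLV} = \frac{1}{N}\lvert\sum_n e^{j\theta(n)}\rvert\)
  (phases from the FFT analytic signal) build per-stage
  synchronization networks.

## Filtering policy and numerics

**Zero-phase everywhere.** Every IIR filter is applied
forward–backward. The analyses are offline and the central claim is a
*temporal ordering* (Sv DC dispersion precedes LF/HF onsets), so group
delay must not bias latencies. Consequences, documented and tested:
the effective order doubles and the gain at the design cutoff is 1/2
rather than \(1/\sqrt{2}\).

**Biquad cascades, not polynomial filters.** At a 1024 Hz sampling
rate the 0.01 Hz band edge places poles at \(|z| \approx 0.99997\);
the expanded transfer-function form is numerically unstable on long
records (outputs diverge), while a cascade of second-order sections
built from the closed-form Butterworth poles via the bilinear
transform is well behaved. All designs use that realization; the
response curves are cross-checked against `signal::butter()` in the
test suite at cutoffs where the polynomial form is stable, and
`filter_response()` exposes the exact zero-phase gain used as the
oracle in filter-contract tests.

**Edge handling.** Before filtering, signals are padded by odd
(point-symmetric) reflection over one settling length — three periods
of the lowest band edge, capped at 60 s — and trimmed afterwards, so
start-up transients of the very low edges do not contaminate onset
estimates on minutes-long segments.

**Which signal feeds the Sv DC filter.** Two uses, two inputs, on
purpose:

* *Energy ratios* take both numerator and denominator from the fully
  preprocessed chain (notch, then 0.01–300 Hz band-pass), keeping the
  ratio in \([0, 1]\).
* *Timing and fluctuation analyses* (dispersion onset, lead ranking)
  take the Sv DC directly from the notch-filtered signal, i.e. the
  defining 0.5 Hz low-pass applied to the original recording. The
  zero-phase 0.01 Hz high-pass is effectively 8th order; on a
  quasi-static ictal shift lasting on the order of 100 s it removes
  most of the energy *and*, being acausal, smears the removed
  component tens of seconds backward in time — which would corrupt
  exactly the latency the dispersion analysis measures. Static
  electrode offsets are harmless on this path because dispersion
  references each lead to a baseline interval and the ranking centers
  each lead before scoring.

**Degenerate inputs.** Zero-energy signals yield missing (`NA`)
correlations and energy ratios, never silent zeros; constant signals
make the cross-correlation undefined (warning + `NA`); a zero
baseline MAD in the onset detectors falls back to an absolute floor
with a warning; windows are half-open \([t_0, t_1)\) with sample *i*
covering \([i/f_s, (i+1)/f_s)\), so adjacent windows tile exactly.

## Preprocessing rules

The fixed chain is a 50 Hz notch (RBJ biquad, Q = 30, hand-designed
because no installed package ships a notch designer), a 0.01–300 Hz
4th-order Butterworth band-pass, and numeric artifact screening:

* *drift* — moving-median baseline (window = `drift_min_s`) outside
  ±100 µV for at least `drift_min_s` (default 10 s; the voltage rule
  is standard clinical practice, the duration is this package's
  choice);
* *discontinuity* — any sample-to-sample jump above `jump_uV`
  (default 500 µV);
* *clipping* — pinned at the amplitude extreme beyond ±100 µV for
  ≥ 1 s.

Flagged channels are excluded from every per-lead statistic but kept
in files; reports carry both totals. Two placement details matter:
the screening runs on the *notch-filtered* signal (the broadband
high-pass removes exactly the baseline offsets the drift rule looks
for), and inside `run_ictal_analysis()` it sees the *pre-ictal*
segment only — a genuine ictal DC shift of a few hundred µV would
otherwise trip the drift rule on precisely the leads the analysis is
about.

## What the synthetic generator emulates

No public recordings accompany this kind of clinical SEEG study, so
the package ships a seeded phenomenological generator
(`sim_config()`, `generate_background()`, `inject_seizure()`,
`generate_interictal()`, `generate_study()`) that reproduces the
statistical structure each analysis stage assumes, with ground truth
for parameter-recovery testing. Per lead it sums:

* **Background** — pink (\(1/f\)) noise at 10 µV RMS, a weak shared
  pink component (30%) and a weak common 10 Hz rhythm (10%). The
  lead-specific part is high-passed at 0.03 Hz: very slow interictal
  potentials reach all contacts through the volume conductor, so in
  real recordings the ultra-slow trend is shared and lead traces stay
  consolidated. (Without this, independent per-lead very-low-frequency
  drift makes any fixed-baseline dispersion detector fire on pure
  background.)
* **Ictal Sv DC offset** — per lead, a signed plateau (magnitudes
  drawn from 100–250 µV, random signs so the field *disperses* rather
  than shifts; 1.5× on designated SOZ leads) with a 10-s raised-cosine
  rise starting `dc_lead_time_s` (default 20 s) before that lead's
  fast activity, and a 20-s raised-cosine return to baseline after
  seizure end. A bounded-support return (rather than an asymptotic
  exponential) makes the ground-truth re-convergence time exact:
  seizure end + fall time. Riding the plateau is a slow in-band
  fluctuation (0.05–0.25 Hz, 0.9× the offset magnitude): physiological
  ictal slow activity is not a clean step, and it is this in-band
  component that carries the Sv DC energy through the 0.01 Hz
  high-pass of the preprocessing chain.
* **Ictal fast activity** — a 3 Hz rhythm (40 µV RMS, slight frequency
  jitter) plus an 80–250 Hz LVFA burst (20 µV RMS), gated from each
  lead's onset. *Pathway* mode staggers onsets by
  `inter_lead_delay_s` (2 s) in a fixed spatial order (contact index,
  then electrode letter); *volume* mode starts all leads together. In
  both modes a common ictal source is mixed in with a fraction
  ramping across the seizure — to 1.0 in volume mode (late-stage
  cross-lead correlation approaches 1, the volume-conduction
  signature) and to 0.4 in pathway mode (synchronization rises but
  stays moderate).
* **Interictal structure** — configured active intervals multiply the
  signal energy by `active_gain` (default 4, i.e. amplitude ×2, so
  the 100%-over-baseline rule fires decisively), and SOZ leads carry
  `soz_fluctuation_gain` (default 5) times the lead-specific
  sub-0.5 Hz fluctuation around the shared trend.

Amplitude defaults were fixed once so that the default ictal
configuration lands in the reported dominance regime — a majority of
leads with Sv DC energy ratio ≥ 60% over the 4-min peri-ictal window,
pooled across seizures — and were not revisited afterwards.

**What it does not emulate.** No biophysics (no ion dynamics, no
conductance-based sources), no electrode geometry, no authentic
artifact morphologies, no inter-patient variability in spectra, and
Gaussian noise throughout. Passing recovery tests therefore shows the
*analysis machinery* is correct and well calibrated under the stated
structure; it is not evidence about clinical localization accuracy on
real data.

## Design choices in ambiguous corners

* Montage: signals are analyzed as recorded (referential); no
  re-referencing is applied or assumed.
* Annotations travel in a sidecar TSV (`onset_s`, `duration_s`,
  `label`) next to EDF and delimited files; the EDF writer emits
  plain 16-bit EDF, not EDF+ timestamped-annotation channels, keeping
  the format plumbing small and fully round-trip-testable.
* Active-phase post-processing merges runs separated by less than
  `merge_gap_s` (6 s) *before* dropping runs shorter than `min_dur_s`
  (12 s) — the usual event-detection order, so a long event fragmented
  by one sub-threshold window survives.
* Sliding-energy windows default to non-overlapping (hop = window);
  threshold comparisons are inclusive (≥) throughout.
* Stage boundaries default to equal thirds of the seizure span;
  explicit boundaries are accepted. PLV uses one window per stage
  (no sub-windowing) and defaults to the HF band, where ictal
  synchronization is most discriminating; any band can be selected.
* The 1-h energy-ratio convention uses hour-long windows with the
  same formula (numerator and denominator over the same hour).
* The cross-lead trend for lead ranking is the median, not the mean,
  so one extreme (epileptogenic) lead does not drag the trend it is
  scored against; Sv DC series are reduced to 0.25-s window means
  before scoring (the band is limited to 0.5 Hz, so nothing is lost).

## Problem sizes used for validation

The recovery studies in the test suite use a compact montage — two
electrodes with three contacts (six leads, two designated SOZ), 5-min
ictal records (onset at 180 s) and 8–10-min interictal records at the
full 1024 Hz sampling rate — sizes chosen so that multi-seed studies
(20 seeds for latency and active-phase recovery, 50 for lead ranking)
remain quick on a laptop while preserving the full seizure structure.
The bundled study scripts under `analysis/` run the default 12-lead,
8-min configuration.

## Known limitations

* The dispersion onset rule (median + 3 MAD, sustained 10 s) is a
  detector built for this package; the threshold constants are
  configurable and no claim is made that they are optimal for
  clinical data.
* Dispersion across *all* leads is the default; a per-electrode
  grouping is available via subsetting but no within-shaft weighting
  is implemented.
* The EDF reader handles plain EDF with a uniform sampling rate;
  EDF+ discontinuous files and per-channel rates are rejected rather
  than resampled.
* Energy ratios depend on the preprocessing band edges; with the
  defining 0.5 Hz low-pass applied to an unfiltered signal containing
  large static offsets, ratios can only be interpreted after offset
  removal (the pipelines handle this, direct calls must).
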