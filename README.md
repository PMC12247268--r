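# svdcfield

Analysis of the **slow-varying DC field** (Sv DC, 0.01–0.5 Hz) of
multichannel intracranial EEG — the infraslow component that standard
clinical review filters discard, which shifts and *disperses* across
leads at seizure onset, before the fast activity electrophysiologists
read.

The package is aimed at clinical neurophysiology / iEEG methods work:
it implements the full analysis chain as tested, reusable functions,
and — because recordings of this kind are not publicly deposited — a
seeded synthetic SEEG generator with ground truth that every stage is
validated against.

## What it computes

* **Band decomposition** — Sv DC via the defining 2nd-order
  Butterworth low-pass at 0.5 Hz (zero-phase), LF (0.5–40 Hz) and HF
  (40–300 Hz) via 4th-order band-passes; plus the equivalent 2-s
  piecewise-mean DC definition.
* **Energy dominance** — per-lead band energy ratios
  `E_svdc / E_total` over the 4-min peri-ictal window (sum of squared
  samples; denominator from the full 0.01–300 Hz preprocessed
  signal), and pooled lead fractions at the ≥ 60% / ≥ 90% thresholds.
* **Dispersion & onset ordering** — the cross-lead spread of
  baseline-referenced Sv DC per 2-s window, its onset
  (median + 3·MAD, sustained ≥ 10 s), peak and re-convergence, and
  latencies against LF/HF sliding-energy onsets.
* **Interictal phases** — 6-s sliding-window energy vs. the
  preceding-hour baseline; windows ≥ 2× baseline (a 100% increase)
  form *active* phases; stable-vs-active Wilcoxon rank-sum per lead;
  leads ranked by Sv DC fluctuation around the cross-lead median
  trend (epileptogenic-zone candidates rank first).
* **Propagation** — normalized autocorrelation
  `ρ(τ) = ∫ s(t)s(t+τ)dt / ∫ s²(t)dt`, mean-centered
  cross-correlation, per-stage (thirds-of-seizure) correlation, and
  phase-locking value networks
  `PLV = |Σₙ exp(jθ(n))| / N` with phases from the analytic signal.

## Worked example

Simulate a default synthetic seizure (12 leads, 8 min, seizure at
300 s whose Sv DC offsets begin 20 s before the fast activity) and run
the full ictal analysis:

```r
library(svdcfield)
cfg <- sim_config(seed = 1)
sim <- inject_seizure(generate_background(cfg), cfg)
rep <- run_ictal_analysis(sim$recording)

rep$threshold_summary
#>   threshold count n_leads fraction pct
#> 1       0.6    12      12        1 100
#> 2       0.9     0      12        0   0

str(rep$ordering)
#> List of 6
#>  $ svdc_onset        : num 280
#>  $ lf_onset          : num 298
#>  $ hf_onset          : num 300
#>  $ latency_svdc_to_lf: num 18
#>  $ latency_svdc_to_hf: num 20
#>  $ svdc_first        : logi TRUE

rep$staged_correlation
#>   stage  t0  t1        rho
#> 1     1 300 330 0.05223204
#> 2     2 330 360 0.37447552
#> 3     3 360 390 0.69051659
```

Reading this: every lead concentrated ≥ 60% of its peri-ictal energy
below 0.5 Hz; the Sv DC dispersion onset was detected at 280 s —
20 s before the HF (LVFA) onset at 300 s, recovering the injected
lead time — and the cross-correlation between the seizure-onset lead
and the most distant lead rises stage by stage as the seizure
recruits a common source (this was a pathway-mode seizure; in volume
mode the final stage approaches 1).

The numbered scripts under `analysis/` run the same machinery as a
small study — simulation, ictal energy, onset ordering, interictal
phases, propagation — writing their tables under `results/`:

```sh
Rscript analysis/01_simulate_study.R
Rscript analysis/02_ictal_energy.R   # ... through 05
```

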