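# imcoh — intermuscular EMG–EMG coherence analysis

`imcoh` is an R package for frequency-domain analysis of paired surface
electromyography (EMG), built for questions like: *do two muscles share an
oscillatory neural drive, in which frequency band, and does that drive
differ between conditions?* Shared drive — for instance the
reticulospinal-related drive implicated in startle-type responses —
reaches the rectified EMG as correlated envelope modulation, so coherence
between rectified channels peaks at the drive frequencies, typically
inspected in the high alpha (~10–16 Hz) and beta (~18–31 Hz) bands.

The package implements the full chain:

* **Preprocessing** — full-wave rectification; burst onset detection as the
  earliest post-stimulus excursion beyond the pre-stimulus baseline mean by
  *k* baseline SDs sustained for a minimum duration (presets: 1 SD / 2 ms
  for startle, 2 SD / 5 ms for reaction-time and perturbation tasks);
  response incidence; screening so that only segments with sustained
  activity throughout the analysis window (smoothed envelope > baseline
  mean + 2 SD at every sample) enter the spectral stage.
* **Spectral estimation** — per-trial windows (256 samples for startle, 512
  otherwise, at 2000 Hz) mean-subtracted, zero-padded to twice their
  length and DFT-transformed; periodograms averaged over L disjoint
  segments. Coherence
  `R²(λ) = |f_xy(λ)|² / (f_xx(λ) f_yy(λ))`, 95% confidence limit
  `CL = 1 − 0.05^(1/(L−1))`, cumulant density (inverse transform of the
  cross-spectrum, with flat asymptotic bounds), pooling across
  records/participants with the combined L, and a crosstalk diagnostic
  (zero-lag cumulant peak + broadband coherence).
* **Statistics** — the χ² extended difference-of-coherence test per bin,
  `2(Σᵢ Lᵢẑᵢ² − (Σᵢ Lᵢẑᵢ)²/Σᵢ Lᵢ)` on Fisher-transformed coherencies
  `ẑ = tanh⁻¹|R|` against `χ²(α, k−1)`, and band means (Fisher-transformed
  per bin, then averaged over the band's bins).
* **Synthetic EMG** — a generator producing paired band-limited carrier
  noise amplitude-modulated by configurable common/private narrowband
  drives, trapezoidal bursts with log-normal onset latencies, optional
  condition-gated drive and linear crosstalk, with full ground truth.

The `analysis/` directory contains numbered drivers
(`01_simulate_cohort.R` … `05_crosstalk_check.R`) that run the standard
analyses end-to-end on synthetic cohorts and write their tables under
`results/`. The methods vignette
(`vignettes/intermuscular-coherence.Rmd`) documents the estimators,
parameter choices and calibration properties in detail.

## Worked example

Simulate a startle-like session — 20 trials, bursts with 59.1 ms median
onset latency, a shared 12 Hz envelope drive at depth 0.5 — and run the
startle preset pipeline:

```r
library(imcoh)

ev  <- trial_events(20, "startle", start_s = 1, spacing_s = 1.2)
cfg <- synthetic_emg_config(
  duration     = 25.5,
  common_drive = list(c(12, 0.5)),
  burst        = burst_spec(onset_median_ms = 59.1, onset_iqr_ms = 4.7,
                            rise_ms = 15, plateau_ms = 220, fall_ms = 40),
  seed = 7)
sim <- generate_emg_pair(cfg, ev)

res <- run_condition(sim$recording, ev, analysis_config("startle"))
res
#> <condition_result> task startle: 13/20 trials -> L = 13 segments
#> <coherence_estimate> 257 bins (0-1000.0 Hz), L = 13, 95% CL = 0.2209
#>   12 bin(s) above CL; peak 0.819 at 11.72 Hz
```

The pooled coherence peaks at 11.72 Hz — the frequency bin nearest the
configured 12 Hz drive on the 3.90625 Hz grid — with the 95% confidence
limit 0.2209 determined solely by the 13 accepted segments
(`1 − 0.05^(1/12)`). Seven trials were rejected by the sustained-activity
screen, which also catches trials whose automatic onset was unreliable.
Band summaries use the grid-resolved presets:

```r
band <- resolve_band(11.7, 15.6, res$coherence$freq, "high_alpha")
band$bin_freqs_hz
#> [1] 11.71875 15.62500
band_mean(res$coherence, band)   # mean tanh^-1|R| over the band's bins
#> [1] 1.271199
res$crosstalk$flag               # narrowband drive is not crosstalk
#> [1] FALSE
```

Two conditions are compared with `run_comparison()` (per-bin χ² doc test
plus a participant × task × band long table of band means, ready for
mixed-model software), and `run_moving_window()` repeats a two-condition
comparison with the analysis window shifted 0–80 ms after muscle onset in
10 ms steps.

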