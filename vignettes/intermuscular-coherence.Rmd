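---
title: "Methods: intermuscular EMG-EMG coherence with pooled confidence limits"
author: "imcoh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intermuscular EMG-EMG coherence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imcoh)
```

## The problem

When two muscles receive a shared oscillatory neural drive, the drive is
visible as correlated modulation of their surface-EMG envelopes.
Full-wave rectification of the EMG demodulates each channel's envelope, and
coherence between the rectified channels then peaks at the drive
frequencies. `imcoh` implements the complete analysis chain for paired
surface-EMG recordings — burst onset detection, sustained-activity segment
screening, zero-padded spectral estimation, coherence with segment-count
confidence limits, cumulant density, pooling across participants, a
chi-squared difference-of-coherence test, and frequency-band summaries —
together with a synthetic-EMG generator that provides ground truth for
every stage. The scientific motivation is the localisation of
reticulospinal-related drive in the high alpha band (roughly 10–16 Hz) of
intermuscular coherence during startle-type responses.

## Estimators

For each accepted trial, a window of $N$ rectified samples per channel is
mean-subtracted, zero-padded to $P$ samples and discrete-Fourier
transformed. Averaging the periodogram products over $L$ disjoint segments
(one per trial) gives auto-spectra $f_{xx}, f_{yy}$ and the cross-spectrum
$f_{xy}$, from which:

* **Coherence** $R^2_{xy}(\lambda) = |f_{xy}(\lambda)|^2 /
  (f_{xx}(\lambda) f_{yy}(\lambda)) \in [0, 1]$ per frequency bin.
* **Confidence limit** $CL = 1 - \alpha^{1/(L-1)}$ at level $\alpha = 0.05$:
  the upper null quantile of estimated coherence under independence, a
  function of the segment count only. Pooled estimates aggregate the
  spectra with segment-count weights — exactly equivalent to treating all
  $\sum_i L_i$ segments as one record — and use the combined count in $CL$.
* **Cumulant density** $q_{xy}(u)$, the inverse transform of the two-sided
  cross-spectrum: time-domain correlation as a function of lag $u$
  (positive lag = second channel lags the first). Flat confidence bounds
  use the asymptotic independence variance
  $\mathrm{var}(q) = (2\pi/P)^2 \sum_k f_{xx}(k) f_{yy}(k) / L$, which
  follows from the per-bin variance $f_{xx}f_{yy}/L$ of the cross-spectral
  estimate and the (approximate) independence of bins.
* **Difference-of-coherence (doc) test**: with
  $\hat z_i = \tanh^{-1}|R_i|$ the Fisher-transformed coherency of group
  $i$ from $L_i$ segments, the per-bin statistic
  $2\left(\sum_i L_i \hat z_i^2 - (\sum_i L_i \hat z_i)^2 / \sum_i L_i\right)$
  is compared against $\chi^2_{\alpha, k-1}$.
* **Band means**: the per-bin Fisher-transformed coherency magnitudes are
  summed over a band's bins and divided by the bin count (an untransformed
  variant is available via `transform = FALSE`).

### Segment geometries, grids and bands

Two geometries cover the standard tasks, both at 2000 Hz sampling:

| task | $N$ | $P$ | plotted grid | underlying resolution |
|---|---|---|---|---|
| startle | 256 (128 ms) | 512 | 3.90625 Hz | 7.8125 Hz |
| all others | 512 (256 ms) | 1024 | 1.953125 Hz | 3.90625 Hz |

Zero padding interpolates the spectrum onto the finer plotted grid without
adding information; significance and the doc test are reported on all
plotted bins, but the underlying resolution remains `rate / N`. Band edges
are grid-dependent: high alpha is 11.7–15.6 Hz (two bins) on the startle
grid and 9.8–15.6 Hz (four bins) otherwise; beta is 19.5–31.3 Hz and
17.6–31.2 Hz respectively. `resolve_band()` selects the inclusive bin set
after rounding bin frequencies to 0.1 Hz, the precision at which band
edges are conventionally stated.

### Onset detection and segment screening

Onset is the earliest post-stimulus sample at which the rectified signal
exceeds the pre-stimulus baseline mean (100 ms window) by `k_sd` baseline
standard deviations continuously for `min_duration_ms`: 1 SD / 2 ms for
startle, 2 SD / 5 ms for reaction-time and perturbation tasks. Ties at
sample resolution resolve to the earliest sample; the search window
defaults to 1000 ms (configurable — the original procedure is silent on
this and relied on visual inspection). A manual-correction column
(`onset_override_ms`) in the events table substitutes for visual
correction; there is no GUI.

A segment enters the spectral stage only if, on both channels, the
smoothed rectified envelope exceeds baseline mean + 2 SD at **every**
sample of the analysis window. The smoothing (10 ms moving RMS,
configurable) is a deliberate interpretation: raw rectified EMG touches
zero between motor-unit potentials, so a samplewise test on raw samples
would reject essentially everything. Whether the original criterion used
raw or smoothed rectified EMG is not stated; users should be aware of this
choice.

## The synthetic generator

Each channel is band-limited Gaussian carrier noise (20–450 Hz, the
dominant surface-EMG band, inside a 2–1000 Hz acquisition passband at
2000 Hz) multiplied by an envelope
$1 + \sum_j d_j \sin(2\pi f_j t + \phi_j)$. Common-drive components share
$\phi_j$ (and optionally a configurable lag) across channels; private
components draw independent phases. Trial bursts scale the amplitude by a
trapezoid (linear rise, plateau, linear fall) whose onset latency is drawn
from a log-normal matched to a (median, IQR) pair — log-normal because
response latencies are positive and right-skewed; the closed-form fit is
`lnorm_params_from_median_iqr()`. Latency medians default to the
startle-like 59.1 ± 4.7 ms (median ± IQR) and, for the reaction-time
conditions, 105.0 ± 12.9 ms (loud stimulus) versus 174.8 ± 37.1 ms
(moderate stimulus). Crosstalk is injected as instantaneous linear mixing
$(1-c)\,x_i + c\,x_j$. Everything is deterministic given the seed.

What the generator emulates: envelope-level common drive (the quantity
rectified-EMG coherence measures), burst timing and incidence,
baseline-to-burst amplitude ratios, electrode crosstalk. What it does not:
motor-unit spike trains and recruitment, force/kinematics, habituation
dynamics beyond a per-trial incidence probability, nonstationary baseline
tone, movement artifacts, and amplitude units (outputs are unitless, since
electrode gain is hardware-specific). Tests passing on this generator
validate the estimators' statistical behaviour, not the physiological
claims one might attach to real recordings.

For condition-specific drives (e.g. a drive present only after
loud-stimulus onsets), the drive can be gated to a post-onset interval of
the burst trials of selected conditions (`drive_gate_ms`,
`drive_conditions`), which lets one recording carry randomly interleaved
trials of both stimulus types, as in a real session.

## Design choices and calibration notes

These points were established with the package's own test suite and
acceptance script; none of them are claims about external data.

* **Pooling.** Segment-weighted spectral aggregation is the default
  because the pooled confidence limit uses the combined segment count,
  which is consistent with treating all segments as one record. The
  alternative — aggregating Fisher-transformed per-record coherencies — is
  available via `pool_records(method = "fisher")`; the two agree closely
  when per-record coherences are similar, and only the spectra route
  yields pooled spectra for the cumulant.
* **Per-segment mean subtraction** suppresses the 0 Hz bin, which would
  otherwise be dominated by the large DC component of rectified bursts.
  Bins whose power is numerically indistinguishable from zero are flagged
  (`zero_power`) and carry coherence 0.
* **doc-test calibration.** At genuinely nonzero coherence the statistic
  holds its nominal level (empirically ~5% at true coherence 0.25,
  $L = 100$ per group). At true coherence near zero it is strongly
  conservative (~0.4% empirically): $\tanh^{-1}|\hat R|$ has variance
  $\approx (1 - \pi/4)/L$ there rather than the $1/(2L)$ the asymptotics
  assume. Calibration checks therefore use a shared-signal process with
  flat true coherence 0.25. No across-bin multiplicity correction is
  applied by default (per-bin reporting is the field's convention); a
  Bonferroni option exists. Expect ~5% of null bins to flag.
* **Onset accuracy depends on the preset and the signal model.** On
  noiseless steps recovery is exact to the sample. With additive noise at
  SNR 3 the 1 SD / 2 ms rule keeps the median error at 0 ms. The stricter
  2 SD / 5 ms rule is systematically late on gradual-rise bursts (it
  cannot fire until a 5 ms run clears the threshold, ~15 ms after envelope
  onset for a 15 ms rise), and the 1 SD / 2 ms rule applied to
  continuously active baselines without manual correction saturates with
  false positives over long search windows. Incidence estimation on the
  generator therefore uses the 2 SD / 5 ms rule over a 200 ms response
  window, where it is empirically unbiased.
* **Early-drive moving-window scenario.** The validation scenario gates
  the 12 Hz drive (depth 0.5) to the first 80 ms after loud-stimulus
  onsets. 80 ms was chosen by an a-priori power calculation so that the
  256 ms analysis window still overlaps enough drive at a 40 ms offset to
  be detectable at $L \approx 450$, reproducing the published pattern of
  early-offset-only significance; a 50 ms gate loses detectability already
  at 20–30 ms offsets because the window-drive overlap shrinks linearly
  with offset.
* **Crosstalk flag.** Both components must hold: global $|q|$ maximum
  within ±2 ms of zero lag and above the independence bounds, and more
  than 50% of bins up to 100 Hz above the CL. A strong narrowband drive
  with rectification harmonics occasionally (order 5% of replicates at
  depth 0.5, $L = 50$) pushes the breadth fraction past 0.5; diagnostics
  expose both components so borderline cases can be inspected.
* **Segment independence.** The confidence limit assumes independent
  segments; the pipeline takes one disjoint segment per trial. Abutting
  segments cut from one continuous realization are slightly dependent
  (the carrier's correlation time is a few ms), which inflates CL
  exceedance slightly; calibration fixtures therefore leave gaps between
  cut segments.

## Problem sizes

The shipped tests and the acceptance script use: CL calibration at
$L \in \{20, 100, 500\}$ with 635–1270 independent bins each; drive
recovery over 100 replicates of $L = 100$ segments; doc type-I over 2032
bins at $L = 100$ per group; onset accuracy over 200 bursts; the
moving-window scenario at 10 sessions × 45 trials per condition
($L \approx 450$ pooled per condition, nine offsets); crosstalk over 20
replicates per case at $L = 50$. The `analysis/` drivers run smaller
versions of the same analyses (5 participants × 20 trials; 3 sessions for
the moving window) and state so in their output.

## Limitations

* The generator's envelope-modulation model cannot probe motor-unit-level
  phenomena (e.g. rectification's effect on spike-train coherence).
* The cumulant confidence bounds are asymptotic and flat; they are
  slightly conservative at lags where the true autospectral product is
  below average, and the global-maximum test across many lags inflates
  the central-peak component's false-positive rate, which is why the flag
  also requires broadband coherence.
* Linear mixed-effects modelling and ANOVA of band means across
  participants, and hypothesis tests on latencies, are out of scope: the
  band-mean long table is designed to be handed to `lme4`/`stats`
  directly.
* Balance/ankle-style continuous tasks are handled by supplying
  movement-cycle markers as events; the package does not segment
  continuous activity on its own.
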