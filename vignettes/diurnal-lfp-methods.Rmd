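---
title: "Methods: diurnal analysis of chronic LFP band-power streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diurnal analysis of chronic LFP band-power streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronolfp)
```

## What the package models

Chronic-sensing DBS devices log band power — the amplitude of the LFP in
a narrow frequency window, in microvolt-peak units (µVp) — as one
averaged value per 10 minutes, with UTC timestamps, continuously for
weeks. `chronolfp` treats such a stream as a timezone-aware time series
(`band_power_series`) and asks three questions about it:

1. how much of its variance is explained by time of day, and is that
   more than chance (`variance_explained()`,
   `temporal_shuffle_test()`);
2. is the dominant periodicity 24 h (`periodogram()`);
3. how does it relate to sleep/wake structure and to artifacts
   (`in_bed_mask()`, `sleep_wake_contrast()`, `day_night_summary()`,
   `movement_power_table()`).

All clock-based operations (daily detrending, binning, day/night
windows) work in *local civil time*: `to_local_time()` re-labels the UTC
instants in an IANA zone, so daylight-saving days simply contain 23 or
25 hours of samples and are binned by their local clock labels.

## Preprocessing

**Outlier interpolation.** Chronic logs contain sporadic extreme values
whose underlying LFP cannot be recovered, so they are replaced: any
sample with $|z| > 6$ (z computed from the full series mean and sample
SD, $n-1$ denominator) is replaced by linear interpolation between its
nearest non-outlier neighbours, and the pass repeats with recomputed
mean/SD until no sample exceeds the threshold. Design points the
procedure itself does not dictate, fixed here as follows:

* the rule is two-sided by default (spikes can deflect either way after
  normalization); a one-sided flag is provided;
* endpoint outliers, with no valid neighbour on one side, take the
  nearest valid value;
* a zero-variance series is returned unchanged (nothing can be an
  outlier of a constant);
* the operation never changes series length or timestamps, and is
  idempotent — both properties are asserted in the test suite.

**Daily detrending.** Each sample is divided by its own civil day's
median, making every day's detrended median exactly 1; this removes slow
multi-day drift while preserving within-day shape. A mean variant
(per-day mean = 1) exists because correlation analyses between
concurrently logged bands conventionally use it. A day whose statistic
is 0 is an error naming the day, not a silent NaN.

## The time-of-day fit and variance explained

The day is divided into 30-min bins (48 per day; `bin_width` must divide
24 h). The fit value at a bin center is the mean of all samples falling
in that bin across all days; between centers the fit is linear
interpolation. Two open choices and their resolutions:

* **Midnight wrapping.** Clock time is circular, so interpolation wraps
  across midnight by default (the last and first bin centers are
  neighbours). A non-wrapping mode (`wrap = FALSE`) holds the fit
  constant beyond the outermost occupied centers, for parity
  experiments with implementations that treat the day as a line
  segment. On realistic data the two differ only within half a bin of
  midnight.
* **Empty bins** are interpolated across; the fit errors only when all
  samples share a single bin.

VE is $( \operatorname{Var}(x) - \operatorname{Var}(x - f(t)) ) /
\operatorname{Var}(x)$ with sample variances. Because $f$ is an
interpolation, not an orthogonal projection, VE can be marginally
negative on pathological inputs; it is reported as-is, never clamped —
a small negative VE is itself diagnostic of an absent diurnal signal.

**Windowed VE** (`windowed_variance_explained()`) restricts both the fit
and the variances to samples inside a clock window (defaults follow the
convention of a sleep-dominated 00:00–06:00 window and a
waking-dominated 08:00–20:00 window). A pure day/night step therefore
has near-zero windowed VE in both windows while its full-24-h VE is
large; this contrast is what separates sleep/wake-driven structure from
within-epoch structure.

## The temporal shuffling test

Surrogates destroy clock alignment while preserving within-day
structure: each civil day's samples are circularly shifted by an
independent offset. Two details are underdetermined by the idea itself:

* **Shift granularity** is one nominal sample interval (10 min → uniform
  over 144 offsets per day). Any finer granularity would only move
  samples into the same bins.
* **The empirical p** uses the add-one (permutation-inclusive)
  correction, $p = (1 + \#\{VE_{null} \ge VE_{obs}\})/(1 + N)$, so the
  smallest attainable p with $N = 1000$ shuffles is $1/1001$ —
  consistent with reporting "p < 0.001" as a floor.

The test's calibration is itself tested: on 200 null simulations (no
diurnal structure) the rejection rate at $\alpha = 0.05$ must lie in
$0.05 \pm 0.03$ and the p-values must be near-uniform.

## Periodogram

The series is placed on its regular 10-min grid; gaps up to 2 h
(`max_gap`) are linearly interpolated, longer gaps split the record and
each contiguous chunk contributes its own Welch segments. The Welch
estimate uses Hann windows of 4 days at 50% overlap with per-segment
linear detrending; a 4-day window puts the 24-h period exactly on a
frequency bin, so a diurnal peak is never split between bins. The
dominant period is the argmax of power over periods from 2 h to half
the record length. No installed estimator provided Welch averaging, so
`welch_psd()` is implemented in-package on `stats::fft` and is pinned by
a Parseval test (density × frequency step sums to the variance within
5%) and by log-log slope recovery on white and 1/f noise.

## Raw LFP and the µVp convention

In-clinic raw streams (250 Hz) are zero-phase band-pass filtered
4–98 Hz (4th-order Butterworth, forward–backward — the procedure
specifies only the corner frequencies; the order and zero-phase
application are package choices). Band power is reported as
$2\sqrt{2} \times$ RMS of the band-filtered segment: a pure in-band
sinusoid of amplitude $A$ yields $2A$ (peak-to-peak equivalent). The
on-device µVp measure is proprietary, so absolute values are not
comparable to device output; relative (%-of-rest) values are the
supported quantity, and the movement table's rest row is 100% by
definition. Epochs sharing a label are averaged with equal weight per
epoch (not per sample), so repeating an identical epoch does not move
the table.

The global wavelet spectrum uses a Morlet mother wavelet with
center-frequency parameter 6 over 60 log-spaced frequencies in 4–98 Hz,
power averaged over time. It is cross-checked against the Welch peak
location on stationary input.

## Small-sample tests

The exact Wilcoxon signed-rank p is computed from the full null
distribution of the positive-rank sum over all $2^n$ sign assignments
(by convolution over the ranks, identical to enumeration; mid-ranks
handle ties, zeros are dropped). Two-sided p is
$2\min(P(W \ge w), P(W \le w))$ capped at 1. For $n = 9$ this gives
$p = 6/512 = 0.0117$ at $W = 43$ and $2/512 = 0.0039$ at $W = 45$; the
implementation is checked against `psignrank` for untied ranks and a
Monte-Carlo sign-flip approximation for tied ones. Exactness is limited
to $n \le 25$; beyond that a user should use the standard normal
approximation in `stats::wilcox.test`.

## The synthetic-data generator

The generator defines the conditions under which the pipeline is
validated; its defaults are fixed once and are not tuning knobs.

* **Deterministic profile:** a day level and a night level (defaults 4
  and 2 µVp — a 2:1 waking/sleep contrast of the magnitude seen in
  subthalamic beta logs) joined by logistic ramps around a sleep window
  (default 00:00–06:00, ramp width 30 min, since real transitions span
  one sample to an hour or two); optionally a smooth 24-h cosine
  multiplier peaking at 15:00 and a slow linear drift.
* **Noise:** multiplicative lognormal, scaled to mean 1 and
  parameterized by its coefficient of variation (default 0.2). Band
  power is non-negative and right-skewed with day/night histograms that
  are roughly lognormal on a log axis, which this reproduces; no
  amplitude distribution for real chronic samples is published, so this
  is a plausible choice, not a fitted one.
* **Outliers:** uniformly placed spikes of `outlier_scale` ×
  `day_level`, sized to trip the $|z|>6$ rule when configured.
* **Dual-band streams:** a fraction `artifact_weight` of each band's
  log-noise variance is drawn from a shared Gaussian process (broadband
  artifacts hit both hemispheres at once), plus an optional daytime
  burst process (Poisson starts in the waking window, exponential
  durations, multiplicative elevation) that produces the bimodal
  daytime histogram characteristic of dyskinesia-affected recordings.
* **Raw LFP:** a sinusoid at the beta peak on 1/f-shaped Gaussian
  noise, with additional 1/f-shaped broadband noise injected during
  labelled artifact epochs.

Because noise is multiplicative, the diurnal variance fraction of a
generated stream is available in closed form
(`diurnal_variance_fraction()`): with noise-free profile $p(t)$ and
noise CV $c$, the fraction is $\operatorname{Var}(p) /
(\operatorname{Var}(p) + \mathbb{E}(p^2) c^2)$.
`noise_cv_for_fraction()` inverts this, which is how test streams with
a 40% diurnal component are constructed. Recovery of the fraction by
`variance_explained()` within ±0.05 (20-seed means at 30 days, for
fractions 0.1/0.25/0.5) is an acceptance property.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: the device's proprietary on-chip averaging
and stimulation-artifact spectra; ECG contamination; medication-locked
power surges; missing-data patterns from telemetry dropouts (gaps are
exercised synthetically but not modelled as a process); and
between-patient heterogeneity of diurnal shape. Conclusions about those
require patient recordings.

## Degenerate inputs and tie-breaks

* Zero-variance series: error in `zscore_series()` and
  `variance_explained()`; pass-through in `remove_outliers()`.
* A day with zero median/mean: error naming the day in
  `detrend_daily()`.
* Days not covered by a sleep diary: masked `NA` and excluded, never
  imputed.
* Missing cells in the day × bin matrix stay `NA`, never zero-filled.
* The bimodality flag compares 1- vs 2-component Gaussian mixtures on
  log10 daytime values by BIC (via `mclust`) — a deliberately simple,
  testable stand-in for a qualitative "strongly bimodal" judgement.
* Sleep windows are constrained to ≤ 12 h so that the circular ramp
  geometry is unambiguous.

## Problem sizes used in the test suite

Simulation-backed tests use 30-day streams at 10-min sampling (4320
samples) for parameter-recovery and correlation checks, 10-day streams
for the 200-run type-I calibration of the shuffle test, 20-seed means
for all stochastic expectations, and 20–240 s raw-LFP segments at
250 Hz for spectral checks. These sizes give Monte-Carlo error
comfortably below the asserted tolerances while keeping the default
suite around a minute of CPU.

## Known limitations

* VE is estimated with the same data used to build the fit; with few
  days and many bins it is optimistically biased (the shuffle test,
  which applies the same procedure to surrogates, is the calibrated
  quantity).
* The periodogram's period grid is the reciprocal of a uniform
  frequency grid; periods far above 24 h are sparsely resolved.
* Absolute µVp-equivalent band powers are convention-bound; only
  relative values should be compared across implementations.
* The exact signed-rank test does not implement the normal
  approximation; it refuses $n > 25$ rather than silently switching.
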