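# chronolfp

Diurnal analysis of chronic LFP band-power streams.

## The problem

Implanted deep brain stimulation (DBS) devices with sensing capability log
the power of a local field potential (LFP) frequency band — typically a
5 Hz window around a patient-specific subthalamic beta peak — as one
averaged value every 10 minutes, in microvolt-peak units (µVp), for weeks
at a time. These chronic streams carry strong day/night structure: beta
power falls during sleep and rises during waking hours. They are also
contaminated by sporadic extreme values and by broadband artifacts from
everyday movements, which matters directly for adaptive DBS, where the
sensed band power drives stimulation.

`chronolfp` is for researchers and engineers working with such streams
(or planning closed-loop control on top of them). It provides a tested
pipeline for:

* **preprocessing** — iterative z-score outlier interpolation, z-scoring,
  daily median detrending;
* **diurnal statistics** — 30-min-binned time-of-day fits, the fraction
  of variance explained by time of day, a day-shift temporal shuffling
  permutation test, Welch periodogram periodicity, windowed (day-only /
  night-only) variance explained, day × bin heat-map matrices;
* **sleep/wake epoch analyses** — diary masks, alignment to daily events
  (wake time, first medication intake), day/night value distributions
  with a bimodality check, in-clinic vs long-term comparison;
* **raw-LFP band power** — zero-phase 4–98 Hz filtering, Welch and global
  Morlet wavelet spectra, µVp-equivalent band power, and a
  movement-epoch power table quantifying artifact inflation;
* **small-sample paired tests** — exact Wilcoxon signed-rank (full
  enumeration of sign assignments), paired t;
* **a synthetic-data generator** with known ground truth (diurnal
  variance fraction, sleep windows, outlier positions, shared-artifact
  correlation), so every downstream stage is testable without any
  patient data.

## The central statistic

For a stream $x_i$ with clock times $t_i$, the *time-of-day fit* $f(t)$
is the mean of $x$ in each 30-min clock bin, linearly interpolated
between bin centers (circularly across midnight). The *variance
explained by time of day* is

$$\mathrm{VE} = \frac{\operatorname{Var}(x) - \operatorname{Var}(x - f(t))}{\operatorname{Var}(x)} .$$

Its significance is assessed by a *temporal shuffling test*: each
surrogate applies an independent circular shift (uniform over the day,
in 10-min steps) to each day's samples — destroying clock alignment
while preserving within-day structure — and VE is recomputed; with 1000
surrogates and the add-one correction the smallest attainable p is
$1/1001$ (reported as $p < 0.001$).

## Worked example

```r
library(chronolfp)

cfg <- diurnal_sim_config(n_days = 30, day_level = 4, night_level = 2,
                          sleep_window = c("00:00", "06:00"),
                          noise_cv = 0.25, outlier_rate = 0.002,
                          outlier_scale = 15, seed = 42)
series <- generate_diurnal_series(cfg)

cleaned   <- remove_outliers(series)        # iterate |z| > 6 interpolation
detrended <- detrend_daily(cleaned$series)  # each day's median -> 1

cleaned$report
#> <preprocess_report> 11 outlier(s) replaced in 1 pass(es)

variance_explained(cleaned$series)
#> <variance_explained> VE = 0.4616 (total 1.496, residual 0.8055)

temporal_shuffle_test(cleaned$series, n_shuffles = 1000, seed = 1)
#> <shuffle_test_result> VE = 0.4616, p = 0.000999 (1000 day-shift surrogates)
#>   (smallest attainable p at this shuffle count)

periodogram(detrended)
#> <periodogram_result> dominant period 24.00 h (48 periods searched)

diary <- generate_sleep_diary(cfg, jitter = 0, seed = 1)
sleep_wake_contrast(cleaned$series, diary)$ratio
#> 0.52
```

Reading the output: 11 extreme samples were replaced by neighbour
interpolation; time of day accounts for 46% of the variance of this
simulated stream (the generator's closed-form ground truth for this
configuration is 0.467, via `diurnal_variance_fraction(cfg)`); none of
the 1000 day-shifted surrogates reaches the observed VE, so the test
returns its floor p = 1/1001; the spectral estimate of the detrended
stream is dominated by a 24-h period; and power while in bed is about
half the waking level, matching the configured 2 vs 4 µVp levels.

Exact small-sample test, e.g. nine paired VE values whose
positive-rank sum is 43:

```r
wilcoxon_exact(statistic = 43, n = 9)
#> <test_result> exact Wilcoxon signed-rank (all sign assignments)
#>   W = 43 (n = 9), two-sided p = 0.01172
```

A thin command-line front end over the same functions is installed at
`inst/cli/chronolfp.R` (subcommands `simulate`, `preprocess`, `profile`,
`shuffle-test`, `periodogram`, `compare`, `run`).

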