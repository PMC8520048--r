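# evospike

Spike-train analysis pipeline for comparing **stimulus-evoked** and
**spontaneous** multi-unit activity (MUA), built around the question: what
distinguishes the firing of a face-selective neural population when it is
driven by a consciously seen face from the same population's spontaneous
(prestimulus and resting-state) firing? The answer this analysis family
gives: over long windows (≈150–250 ms) evoked firing dominates outright,
but over very short windows (≈2–20 ms) spontaneous activity regularly
reaches evoked-like intensities — the evoked response is distinguished by
being *sustained*, not by being momentarily more intense.

The package is aimed at electrophysiologists analysing human or animal
microwire MUA recordings with a task session and a task-free resting
session, and at methodologists who want a tested reference implementation
of the window-ranking statistic.

## What it implements

- **Synthetic study generator** (`generate_study()`): seeded inhomogeneous-
  Poisson task + resting sessions for four unit presets (`mu1`, `mu2`
  face-selective with spontaneous bursts; `ctrl` non-selective; `null`
  exchangeability null). The evoked shape is solved by
  `calibrate_evoked_shape()` so the pipeline's own detector recovers the
  reference modulation period, peak time, and condition means.
- **Epoching** (`split_parts()`, `cut_epochs()`): 500 ms baseline + 1250 ms
  trial windows; part-1/part-2 independence split (part 2 estimates, part 1
  compares).
- **Rate estimation** (`smooth_rate()`, `condition_mean_rate()`,
  `rate_histogram()`): instantaneous rates by Gaussian-kernel smoothing
  (FWHM 80 ms, σ = FWHM/2√(2 ln 2)), pooled condition means ± SEM, and
  per-condition normalized rate-distribution histograms with a reported
  tail fraction.
- **Cluster-based permutation tests** (`cluster_test_vs_baseline()`,
  `cluster_test_between()`, `modulation_period()`): per-bin t on smoothed,
  baseline-corrected epochs; contiguous supra-threshold clusters scored by
  summed t (mass); max-cluster-mass permutation null (sign flips /
  label shuffles), two-tailed.
- **Spectra** (`select_segments()`, `psd_segments()`, `condition_psd()`):
  per-trial FFT power of mean-subtracted 500 ms binary-train segments
  (2 Hz resolution), averaged per condition.
- **Window-ranking statistic** (`window_counts()`,
  `top_fraction_spontaneous()`, `window_curve()`,
  `exchangeability_curve()`): pool 70 evoked + 70 spontaneous spike-count
  windows, rank descending, and report the % of spontaneous windows among
  the top K = round(threshold × 140) for thresholds 5/20/35/50% and window
  lengths 2–250 ms; resting onsets bootstrapped 1000×; ties resolved by
  proportional allocation (exact 50% null).
- **Orchestration** (`analysis_config()`, `run_analysis()`, `run_study()`):
  one seed reproduces every table; tidy CSV/JSON outputs and ggplot2
  figures (`autoplot()` methods); a thin CLI wrapper in
  `inst/scripts/run_study.R`.

All user-facing functions take and return tibbles (or small S3 result
objects with `tidy()`/`glance()`/`autoplot()` methods), so stages chain
naturally with the pipe.

## Worked example

```r
library(evospike)

study <- generate_study("mu1", seed = 1)
#> <mua_study 'mu1' (seed 1): task 13645 spikes/280 trials, resting 5133 spikes>

results <- run_analysis(study, analysis_config(preset = "mu1", seed = 1))
results
#> <mua_results: preset 'mu1', seed 1>
#>   modulation period [82, 747] ms, peak 174 ms (p = 0.000999)
#> # A tibble: 3 × 4
#>   condition   mean_rate    sem n_samples
#>   <chr>           <dbl>  <dbl>     <int>
#> 1 faces            48.0 0.102      46620
#> 2 prestimulus      16.7 0.0723     35000
#> 3 resting          14.7 0.0216    349864
```

The part-2 data found one significant evoked cluster spanning 82–747 ms
after stimulus onset with its t-statistic peak at 174 ms (the generator's
calibration targets are 84–751 ms and 176 ms); the minimal permutation
p-value with 1000 permutations is 1/1001 ≈ 0.001. On the independent
part-1 data, the mean instantaneous rate over that period is ~48 spikes/s
for faces versus ~17 (prestimulus) and ~15 (resting) spikes/s.

```r
tidyr::pivot_wider(tidy(results$window_resting),
                   names_from = threshold, values_from = pct_spontaneous)
#> # A tibble: 9 × 5
#>   length_ms `0.05`  `0.2` `0.35` `0.5`
#> 1         2 6.31   21.4   36.7   42.9
#> 2         5 2.00    8.95  15.8   31.6
#> 3        10 0.702   2.74  12.1   22.0
#> 4        20 0.672   2.23   4.34  14.9
#> 5        50 1.48    3.06   5.74  13.4
#> 6       100 3.00    3.09   5.74  12.3
#> 7       150 0.808   1.37   3.64  11.3
#> 8       200 0.416   0.817  2.18   9.71
#> 9       250 0.0607  0.301  0.920  6.39
```

Each cell is the percentage of resting-state windows among the top-ranked
firing windows (1000 bootstrap draws of resting onsets). At 2 ms windows,
spontaneous activity still claims ~6% of the very top (5%) ranks; by
200–250 ms it has all but vanished from the top 35% — the sustained-firing
signature. `autoplot(results$window_resting)` draws the curve;
`run_study(config, dir)` writes the dataset, all result tables and figures
to `dir`.

## Vignette

`vignettes/evoked-vs-spontaneous.Rmd` documents the model, the evoked-shape
calibration, every tunable parameter with units and defaults, the tie
handling of the ranking statistic, numerical choices, and what the
synthetic generator does and does not emulate about real recordings.
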