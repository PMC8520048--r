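---
title: "Comparing stimulus-evoked and spontaneous multi-unit firing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing stimulus-evoked and spontaneous multi-unit firing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 7, fig.height = 4.5)
library(evospike)
library(dplyr)
```

## The scientific question

A face-selective neural population in the ventral visual stream fires
vigorously when a face is consciously seen. The same population also fires
spontaneously — during fixation before a stimulus and during task-free rest —
and that spontaneous activity is not accompanied by any face percept. What
property of the firing distinguishes the two? `evospike` implements a
complete analysis pipeline for this comparison on multi-unit activity (MUA):
spike trains recorded as pooled activity of a few nearby neurons on one
microwire, stored simply as spike times at 1 ms resolution.

The pipeline's central measure asks, for a window of a given length, how
often spontaneous firing is competitive with the evoked response: pool an
equal number of evoked and spontaneous spike-count windows, rank them, and
report the percentage of spontaneous windows among the top 5%, 20%, 35% and
50%. If evoked and spontaneous activity were indistinguishable, every
percentage would sit at 50%. The scientifically interesting pattern is that
for long windows (150–250 ms) spontaneous windows essentially vanish from
the top ranks, while for very short windows (2–20 ms) they remain
represented even among the top 5% — sustained firing, not instantaneous
intensity, is what separates the evoked response from spontaneous activity.

Because the motivating clinical recordings cannot be redistributed, the
package ships a calibrated generator that emulates their statistical
structure, making the whole pipeline testable end to end.

## Session layout and the independence split

The emulated task session presents 120 face, 120 scene and 40 object trials
(1 s stimulus preceded by 1.2 s fixation; 2.2 s onset-to-onset; 11 min 23 s
of recording, with a quiet tail after the last trial). The resting session
is 5 min 50 s (350 s) of task-free recording. Epochs cover 500 ms before to
1250 ms after each onset. Object trials are never analysed.

All inferential parameters — the significant modulation period and its peak
— are estimated on the *second* part of the task session (everything after
the first 350 s, chosen to equal the resting-session duration). Every
evoked-versus-spontaneous comparison then uses the *first* part only, whose
70 face trials supply the evoked windows. `split_parts()` assigns a trial by
its onset time; a trial whose epoch straddles the 350 s boundary belongs to
part 1 if its onset precedes the boundary (the recordings give no reason to
prefer another rule, and the rule touches at most one trial).

## The synthetic units

`generate_study(preset, seed)` produces a task session (spike train + event
table) and a resting session for one of four unit presets:

| preset | character | fixation rate | resting rate | evoked period mean |
|--------|-----------|---------------|--------------|--------------------|
| `mu1`  | face-selective, bursty rest | 15.9 sp/s | 14.95 sp/s | 48.6 sp/s over [84, 751] ms |
| `mu2`  | face-selective, bursty rest | 14.7 sp/s | 10.38 sp/s | 48.21 sp/s over [91, 768] ms |
| `ctrl` | non-selective | 12.5 sp/s | 12.5 sp/s | none |
| `null` | exchangeability null | 15 sp/s | 15 sp/s | none |

Spikes are drawn from an inhomogeneous Poisson process at 1 ms resolution.
Spontaneous activity is a constant background plus, for the bursty presets,
brief high-rate bursts: burst centres follow a homogeneous Poisson process
at 0.5 bursts/s (active during rest and fixation, not during stimulus
presentation), each adding a Gaussian intensity bump of 60 sp/s peak and
50 ms FWHM, i.e. about 3.19 extra spikes per burst and 1.60 sp/s of added
mean rate. These bursts are what makes short spontaneous windows
occasionally as intense as the evoked response — the phenomenon the
window-ranking statistic quantifies. The background components are set so
the *total* fixation and resting rates equal the table above.

### Calibrating the evoked shape to its detection targets

The face-evoked component is an onset transient (Gaussian bump) followed by
a sustained plateau. Its six shape parameters (plateau edges and height;
transient centre, width and amplitude) are not set by hand: they are solved
at run time by `calibrate_evoked_shape()` so that the *pipeline's own
detector* reproduces the target quantities. Working in closed form with the
expected smoothed epoch profile and the expected per-bin t statistic (for
the part-2 sample size of 50 trials), a Levenberg–Marquardt solve imposes:

* the expected t crosses the cluster-forming threshold exactly at 84 ms and
  751 ms after onset;
* the expected t has zero slope at 176 ms, exceeds the plateau's t level
  there by a fixed prominence margin of 3 (so the observed argmax lands on
  the transient rather than anywhere on the plateau), and stays above
  threshold throughout (one contiguous cluster);
* the mean smoothed intensity over [84, 751] ms equals 48.6 sp/s.

This inversion is necessary because an 80 ms FWHM kernel widens any sharp
intensity step by roughly 35–45 ms on each side before the t trace crosses
its threshold: a naive plateau spanning [84, 751] ms at 48.6 sp/s would be
*detected* as roughly [44, 791] ms, and a flat plateau has no peak at all.
Conversely, the transient must carry enough amplitude that its smoothed
flank, not the plateau edge, dominates the statistic's slope near the peak;
a closed-form feasibility analysis shows weak-transient shapes cannot
satisfy both the 84 ms crossing and a 176 ms maximum. The solved `mu1`
shape has its transient centred near 172 ms (≈ 130 sp/s momentary peak
intensity) and its plateau from ≈ 240 to ≈ 715 ms at ≈ 37 sp/s above
background — a transient-then-sustained time course typical of visual
cortical responses. Scene trials receive the same shape scaled by the
preset's `scene_gain` (0.15 for `mu1`, 0.35 for `mu2`), producing the
face-selectivity contrast; object trials receive none.

Trial order is a uniform permutation at fixed category proportions, rotated
minimally so part 1 contains exactly 70 face trials. Two face trials per
study are flagged as incorrect responses, supporting the optional
exclusion robustness check (`drop_incorrect`, default off).

## Rate estimation

Instantaneous firing rates are the binarized train convolved with a
unit-mass Gaussian kernel of 80 ms FWHM (σ = FWHM/2.3548 ≈ 34 ms, truncated
at ±4σ). Convolution is zero-padded, so session-level summaries exclude a
2σ edge margin; epoch-level baselines keep their edge bins, whose small
deflation (≈ 0.34 sp/s averaged over the 500 ms baseline) is part of the
closed-form model the calibration inverts. Condition means report the
pooled-sample SEM (`sd/sqrt(n_samples)` over all 1 ms rate samples). That
convention matches how such tiny SEMs (hundredths of a spike/s) arise in
reports of this analysis, but pooled samples are autocorrelated over the
kernel width, so this SEM is *not* the sampling error of the mean as an
estimate of the underlying intensity; where a test needs a real sampling
error the package's tests use the count-based Poisson standard error
(including the burst compound-Poisson term for bursty units).

Rate histograms use 1 sp/s bins from 0 to a 100 sp/s display limit and are
normalized per condition by the number of rate samples; mass beyond the
limit is reported separately as a tail fraction, so frequencies plus tail
sum to one.

## Detecting modulation: cluster-based permutation tests

`cluster_test_vs_baseline()` smooths each epoch, subtracts the trial's mean
baseline rate ([-500, 0) ms), computes a per-bin one-sample t across trials
over the trial period, forms contiguous clusters of bins with |t| above the
two-tailed threshold at α = 0.05 (cluster-forming threshold
`qt(0.975, n-1)`), scores clusters by summed t, and compares each observed
cluster mass against the permutation distribution of the maximal absolute
cluster mass under 1000 random sign flips of trial traces. Zero-variance
bins are assigned t = 0. `cluster_test_between()` does the same with a
two-sample pooled-variance t and condition-label shuffling.
`modulation_period()` reports onset, peak (bin of maximal |t| inside the
winning cluster) and offset of the largest-mass significant cluster, or an
explicit all-`NA` "no modulation" row. The α = 0.05 / 1000-permutation /
max-mass choices are the standard configuration for this test family; the
cluster threshold only shapes sensitivity, while family-wise error control
comes from the permutation null.

## Power spectra

Spectra are computed per 500 ms segment and averaged within condition:
faces segments start at the unit's peak-modulation time in each part-1 face
trial, prestimulus segments are each trial's 500 ms baseline, and resting
segments start at uniformly random positions (as many as there are face
trials). The FFT input is the *mean-subtracted binarized train* — not the
smoothed rate, which would imprint the kernel's own transfer function; a
`psd_input = "smoothed"` option exists for comparison. With power defined
as |X|²/(N·Δt) at 2 Hz spacing up to the 500 Hz Nyquist frequency, a
homogeneous Poisson train at rate λ has a flat expected spectrum at λ,
which the test suite verifies against simulation; evoked segments then
stand above spontaneous segments across frequencies in proportion to their
rates. No taper is applied (rectangular window); absolute units matter less
here than the condition contrast, which is the reproducible content of this
analysis.

## The window-ranking statistic

For a window length L (grid: 2, 5, 10, 20, 50, 100, 150, 200, 250 ms):

1. take one evoked window per part-1 face trial, starting at the
   peak-modulation time estimated on part 2;
2. take an equal number of spontaneous windows — resting windows at
   uniformly random onsets (overlaps permitted), or one prestimulus window
   per trial ending at stimulus onset;
3. sum spikes per window (raw counts, no smoothing) — 70 + 70 = 140 values;
4. rank the pooled counts in descending order;
5. report the percentage of spontaneous windows among the top
   K = round(threshold × 140) values, i.e. the top 7, 28, 49 and 70
   windows.

For the resting comparison the random-onset draw is repeated 1000 times and
the statistic averaged (bootstrap); the prestimulus comparison has exactly
one natural window per trial and uses no bootstrap.

Ties dominate short windows (2 ms counts are almost all 0 or 1), and the
ranking is not well defined without a tie rule. The default is
*proportional allocation*: values tied at the cut share the remaining
top-K slots in proportion to group composition. This equals the expectation
over uniformly random tie orders, makes the statistic deterministic given
the counts, and makes the exchangeability null exact: when both groups are
i.i.d. from one distribution the expected statistic is exactly 50% at every
length and threshold. A `tie_policy = "random"` option reproduces per-draw
jitter instead. The test suite checks the proportional rule against
exhaustive enumeration of all tie-consistent rankings on small instances.

Two distinct null summaries matter and are deliberately separate functions:

* `window_curve()` on a non-modulated study is what an analyst sees for a
  control unit: a curve that *fluctuates around* 50%. Its per-cell values
  carry the sampling noise of the 70 fixed trial windows (SD ≈ 10 points at
  the 5% threshold, shrinking to ≈ 3 at 50%), which no amount of resting
  bootstrap removes.
* `exchangeability_curve()` estimates the *expectation* under the shared
  null by simulating fresh Poisson realizations per replicate and taking
  disjoint windows, whose counts are genuinely i.i.d.; it converges to 50%
  within Monte-Carlo error. Reusing one finite record for every replicate
  would instead condition on that record's realized rate and bias the
  5%-threshold expectation by several points, which is why fresh
  realizations are drawn.

## Orchestration and reproducibility

`run_analysis()` wires the stages in dependency order: part 2 →
selectivity and modulation period; part 1 → condition means, histograms,
spectra and window curves, all parameterized by the part-2 estimates. For a
unit with no significant modulation the tables are still produced, aligned
on the raw t-statistic peak (clamped so the longest ranking window fits in
the epoch). `analysis_config()` carries every tunable; a master seed
derives fixed sub-seeds for the four stochastic stages, so configuration
plus one integer reproduces every table byte for byte. `run_simulate()` /
`write_study()` / `read_study()` round-trip datasets through plain CSV +
JSON; `write_results_bundle()` emits one tidy CSV per figure-level result
and `report_figures()` regenerates all figures from those tables alone.

## Problem sizes and numerical choices

The shipped defaults reproduce the full study geometry (120/120/40 trials,
350 s resting, 1000 permutations, 1000 bootstrap draws); a complete `mu1`
simulate-and-analyse run takes a few seconds. The package's own acceptance
checks run the cluster test at its full 1000 permutations, use 200
simulated studies for the type-I-error bound, and 300–1000 bootstrap draws
for curve summaries — sizes chosen so each check pins its statistic well
inside the asserted tolerance. Convolution is FFT-based; kernel truncation
at ±4σ leaves < 10⁻⁴ of kernel mass outside; burst bumps are truncated at
±4σ of their own width. The calibration solve is deterministic (no RNG) and
cached per preset.

## What passing tests do and do not show

The generator emulates: Poisson spiking at the recorded mean rates, a
transient-plus-sustained evoked time course with face selectivity, brief
spontaneous bursts, and the exact session geometry. It deliberately omits:
refractoriness and spike-sorting artefacts, slow non-stationarities (drift,
state changes) in background rate, trial-to-trial amplitude variability of
the evoked response, and any oscillatory structure in spontaneous activity.
Consequently, green tests certify the *pipeline* — that each stage computes
what it claims, that the detector recovers known ground truth at realistic
signal-to-noise, and that the ranking statistic behaves exactly as its
theory predicts under the null — not that real cortical MUA satisfies the
generator's assumptions. On real data the burst model in particular
understates long-range dependence, so real window curves may decline more
slowly with window length than the synthetic ones.

## Known limitations

* Familiarity contrasts (familiar vs unfamiliar stimuli) are out of scope;
  the event tables carry the labels but no analysis uses them.
* Multitaper spectral estimation is not implemented; spectra are
  single-taper (rectangular) by design.
* The pooled-sample SEM convention (above) is reported, not a corrected
  effective-sample-size SEM.
* The cluster test assumes exchangeable trials; slow drift across a session
  would violate the sign-flip null.
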