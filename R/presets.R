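#' Unit firing profile
#'
#' Parameterizes one synthetic multi-unit: a constant background intensity,
#' an evoked elevation for face stimuli (a sustained plateau plus an onset
#' transient), a scene gain, and spontaneous burst statistics. The
#' `evoked_onset`/`evoked_peak_time`/`evoked_offset` fields are the target
#' boundaries and peak of the *detected* modulation period (cluster-based
#' permutation scan on kernel-smoothed rates), and `evoked_mean_rate` is the
#' target mean intensity over that period; the underlying plateau edges and
#' height are solved from these targets by [calibrate_evoked_shape()].
#'
#' @param baseline_rate Background intensity during the task session,
#'   spikes/s, excluding the burst contribution.
#' @param rest_rate Background intensity during the resting session,
#'   spikes/s, excluding the burst contribution.
#' @param evoked_mean_rate Target mean intensity over
#'   `[evoked_onset, evoked_offset]` for face trials, spikes/s. `NA` for a
#'   unit with no evoked modulation.
#' @param evoked_onset,evoked_peak_time,evoked_offset Target modulation
#'   boundaries and peak, ms after stimulus onset.
#' @param scene_gain Multiplier in `[0, 1]` applied to the evoked component
#'   on scene trials.
#' @param burst_rate Rate of spontaneous bursts, bursts/s, during resting
#'   and inter-stimulus (fixation) intervals.
#' @param burst_peak_rate Peak intensity of one burst, spikes/s.
#' @param burst_fwhm Full width at half maximum of the Gaussian burst
#'   intensity bump, ms.
#' @return A list of class `unit_profile`.
#' @export
unit_profile <- function(baseline_rate, rest_rate = baseline_rate,
                         evoked_mean_rate = NA_real_,
                         evoked_onset = NA_real_, evoked_peak_time = NA_real_,
                         evoked_offset = NA_real_, scene_gain = 0,
                         burst_rate = 0, burst_peak_rate = 0,
                         burst_fwhm = 50) {
  stopifnot(baseline_rate >= 0, rest_rate >= 0, burst_rate >= 0,
            burst_peak_rate >= 0, burst_fwhm > 0,
            scene_gain >= 0, scene_gain <= 1)
  modulated <- is.finite(evoked_mean_rate)
  if (modulated) {
    stopifnot(evoked_onset < evoked_peak_time,
              evoked_peak_time < evoked_offset,
              evoked_mean_rate > baseline_rate)
  }
  structure(list(
    baseline_rate = baseline_rate, rest_rate = rest_rate,
    evoked_mean_rate = evoked_mean_rate, evoked_onset = evoked_onset,
    evoked_peak_time = evoked_peak_time, evoked_offset = evoked_offset,
    scene_gain = scene_gain, burst_rate = burst_rate,
    burst_peak_rate = burst_peak_rate, burst_fwhm = burst_fwhm,
    modulated = modulated
  ), class = "unit_profile")
}

#' Expected spikes contributed by one spontaneous burst
#'
#' The Gaussian intensity bump integrates to
#' `peak * sigma_b * sqrt(2 * pi)` spikes with `sigma_b = fwhm / 2.3548` (s).
#'
#' @param burst_peak_rate Peak intensity, spikes/s.
#' @param burst_fwhm FWHM of the bump, ms.
#' @return Expected spike count per burst.
#' @export
spikes_per_burst <- function(burst_peak_rate, burst_fwhm) {
  sigma_s <- burst_fwhm * FWHM_TO_SIGMA / 1000
  burst_peak_rate * sigma_s * sqrt(2 * pi)
}

# Mean intensity added by the burst process where it is active (spikes/s).
burst_mean_rate <- function(profile) {
  profile$burst_rate * spikes_per_burst(profile$burst_peak_rate,
                                        profile$burst_fwhm)
}

#' Session layout specification
#'
#' Defaults describe the study layout emulated by the generator: a task
#' session of 120 face, 120 scene and 40 object trials (1.2 s fixation +
#' 1 s stimulus, total 11 min 23 s), a 5 min 50 s resting session, epoch
#' windows of 500 ms baseline + 1250 ms trial, and a first analysis part
#' equal in duration to the resting session and containing exactly 70 face
#' trials.
#'
#' @param n_face_trials,n_scene_trials,n_object_trials Trial counts.
#' @param fixation_dur,stimulus_dur Fixation and stimulus durations, s.
#' @param epoch_baseline,epoch_trial Epoch window before/after onset, ms.
#' @param task_dur,resting_dur,part1_dur Session durations, s.
#' @param n_face_part1 Face trials required in the first part.
#' @param resolution Bin width, ms.
#' @return A list of class `session_spec`.
#' @export
session_spec <- function(n_face_trials = 120, n_scene_trials = 120,
                         n_object_trials = 40, fixation_dur = 1.2,
                         stimulus_dur = 1, epoch_baseline = 500,
                         epoch_trial = 1250, task_dur = 683,
                         resting_dur = 350, part1_dur = 350,
                         n_face_part1 = 70, resolution = 1) {
  stopifnot(part1_dur <= task_dur, resolution > 0,
            epoch_baseline <= fixation_dur * 1000)
  structure(list(
    n_face_trials = n_face_trials, n_scene_trials = n_scene_trials,
    n_object_trials = n_object_trials, fixation_dur = fixation_dur,
    stimulus_dur = stimulus_dur, epoch_baseline = epoch_baseline,
    epoch_trial = epoch_trial, task_dur = task_dur,
    resting_dur = resting_dur, part1_dur = part1_dur,
    n_face_part1 = n_face_part1, resolution = resolution
  ), class = "session_spec")
}

#' Built-in unit presets
#'
#' Four presets calibrated so that the full pipeline recovers the reference
#' condition means: `mu1` and `mu2` are face-selective units with sustained
#' evoked elevation and spontaneous bursting, `ctrl` is a non-selective unit
#' with constant intensity, and `null` is a constant 15 spikes/s unit used
#' for exchangeability nulls. Background components are chosen so that total
#' fixation-interval rates (background + bursts) equal 15.9 / 14.7 spikes/s
#' and resting totals equal 14.95 / 10.38 spikes/s for `mu1` / `mu2`.
#'
#' @param preset One of `"mu1"`, `"mu2"`, `"ctrl"`, `"null"`.
#' @return A `unit_profile`.
#' @export
#' @examples
#' preset_profile("mu1")
preset_profile <- function(preset = c("mu1", "mu2", "ctrl", "null")) {
  preset <- match.arg(preset)
  burst_mu <- 0.5 * spikes_per_burst(60, 50) # ~1.60 spikes/s where active
  switch(preset,
    mu1 = unit_profile(
      baseline_rate = 15.9 - burst_mu, rest_rate = 14.95 - burst_mu,
      evoked_mean_rate = 48.6, evoked_onset = 84, evoked_peak_time = 176,
      evoked_offset = 751, scene_gain = 0.15,
      burst_rate = 0.5, burst_peak_rate = 60, burst_fwhm = 50),
    mu2 = unit_profile(
      baseline_rate = 14.7 - burst_mu, rest_rate = 10.38 - burst_mu,
      evoked_mean_rate = 48.21, evoked_onset = 91, evoked_peak_time = 173,
      evoked_offset = 768, scene_gain = 0.35,
      burst_rate = 0.5, burst_peak_rate = 60, burst_fwhm = 50),
    ctrl = unit_profile(baseline_rate = 12.5),
    null = unit_profile(baseline_rate = 15)
  )
}

#' @rdname preset_profile
#' @export
preset_names <- function() c("mu1", "mu2", "ctrl", "null")

# ---- evoked-shape calibration ---------------------------------------------

# cache for solved shapes (keyed by preset parameters)
.calibration_cache <- new.env(parent = emptyenv())

# Evoked intensity shape on a bin grid: sustained plateau with fractional
# coverage at its edges plus a Gaussian onset transient. `t_lo` are bin
# start times (ms after stimulus onset), `res` the bin width.
evoked_shape <- function(t_lo, res, cal) {
  centre <- t_lo + res / 2
  coverage <- pmax(0, pmin(cal$plateau_end, t_lo + res) -
                     pmax(cal$plateau_start, t_lo)) / res
  cal$plateau_delta * coverage +
    cal$transient_amp *
      exp(-(centre - cal$transient_centre)^2 / (2 * cal$transient_sigma^2))
}

#' Solve the evoked intensity shape from its detection targets
#'
#' The generator's evoked component is a Gaussian onset transient followed
#' by a sustained plateau. Because the modulation period is *detected* on
#' kernel-smoothed rates with a cluster-forming t-threshold, the detected
#' boundaries sit outside the underlying shape's support and the detected
#' peak sits where the expected t-statistic is maximal. This function
#' inverts that mapping: it computes the generator's expected smoothed
#' epoch profile and per-bin t-statistic in closed form and solves (by
#' Levenberg-Marquardt on the residual vector) for the plateau edges and
#' height and the transient centre, width and amplitude such that
#'
#' * the expected t crosses the cluster-forming threshold exactly at the
#'   target onset and offset,
#' * the expected t has zero slope at the target peak time and exceeds the
#'   plateau's t level there by a fixed prominence margin (so the observed
#'   argmax lands on the transient, not the plateau),
#' * the expected t stays above threshold throughout the period (a single
#'   contiguous cluster), and
#' * the mean smoothed intensity over the target period equals the target
#'   mean rate.
#'
#' @param profile A modulated [unit_profile()].
#' @param spec A [session_spec()].
#' @param n_trials Number of trials feeding the detection (defaults to the
#'   part-2 face-trial count implied by `spec`).
#' @param alpha_cluster Cluster-forming two-tailed alpha.
#' @param fwhm_ms Smoothing kernel FWHM, ms.
#' @return A list with `plateau_start`, `plateau_end` (ms), `plateau_delta`
#'   (spikes/s), `transient_centre` (ms), `transient_sigma` (ms),
#'   `transient_amp` (spikes/s) and the residual norm `deviance`.
#' @export
calibrate_evoked_shape <- function(profile, spec = session_spec(),
                                   n_trials = NULL, alpha_cluster = 0.05,
                                   fwhm_ms = 80) {
  stopifnot(inherits(profile, "unit_profile"), profile$modulated)
  if (is.null(n_trials)) {
    n_trials <- spec$n_face_trials - spec$n_face_part1
  }
  key <- paste(signif(unlist(profile[c(
    "baseline_rate", "evoked_mean_rate", "evoked_onset", "evoked_peak_time",
    "evoked_offset", "burst_rate", "burst_peak_rate", "burst_fwhm")]), 10),
    n_trials, alpha_cluster, fwhm_ms, collapse = "_")
  if (!is.null(.calibration_cache[[key]])) return(.calibration_cache[[key]])

  res <- spec$resolution
  nb <- as.integer((spec$epoch_baseline + spec$epoch_trial) / res)
  t_lo <- seq(-spec$epoch_baseline, by = res, length.out = nb)
  centre <- t_lo + res / 2
  base_idx <- seq_len(as.integer(spec$epoch_baseline / res))
  stim_on <- centre > 0 & centre < spec$stimulus_dur * 1000
  w <- gaussian_kernel(fwhm_ms, res)
  w2 <- w^2
  burst_mu <- burst_mean_rate(profile)
  spb <- spikes_per_burst(profile$burst_peak_rate, profile$burst_fwhm)
  t_crit <- stats::qt(1 - alpha_cluster / 2, df = n_trials - 1)
  base_T <- spec$epoch_baseline / 1000
  bin_at <- function(ms) as.integer(ms / res) + length(base_idx) + 1L
  i_on <- bin_at(profile$evoked_onset)
  i_off <- bin_at(profile$evoked_offset)
  i_pk <- bin_at(profile$evoked_peak_time)
  prominence <- 3   # expected-t margin of the transient peak over the plateau
  headroom <- 0.3   # expected-t clearance above threshold inside the period

  expected <- function(cal) {
    lam <- profile$baseline_rate + burst_mu * (!stim_on)
    lam[-base_idx] <- lam[-base_idx] +
      evoked_shape(t_lo[-base_idx], res, cal)
    s <- conv_same(lam, w)
    m <- s - mean(s[base_idx])
    v <- 1000 / res * conv_same(lam, w2) +
      mean(lam[base_idx]) / base_T +
      profile$burst_rate * spb^2 / base_T
    list(t = m / sqrt(v / n_trials), s = s)
  }
  as_cal <- function(par) {
    list(plateau_start = par[1], plateau_end = par[2],
         plateau_delta = par[3], transient_centre = par[4],
         transient_sigma = par[5], transient_amp = par[6])
  }
  residuals_ <- function(par) {
    if (par[3] <= 0 || par[5] < 5 || par[6] <= 0 || par[1] >= par[2] ||
        par[1] < 0 || par[2] > spec$epoch_trial) {
      return(rep(1e3, 6))
    }
    et <- expected(as_cal(par))
    tt <- et$t
    interior <- tt[(i_on + 20L):(i_off - 20L)]
    plateau_top <- max(tt[(i_pk + 120L):(i_off - 40L)])
    c(tt[i_on] - t_crit,
      tt[i_off] - t_crit,
      mean(et$s[i_on:i_off]) - profile$evoked_mean_rate,
      25 * (tt[i_pk + 1L] - tt[i_pk - 1L]),
      50 * min(0, min(interior) - t_crit - headroom),
      tt[i_pk] - plateau_top - prominence)
  }
  start <- c(profile$evoked_peak_time + 65,
             profile$evoked_offset - fwhm_ms * 0.45,
             profile$evoked_mean_rate - profile$baseline_rate + 1,
             profile$evoked_peak_time - 5, 27,
             2.2 * (profile$evoked_mean_rate - profile$baseline_rate))
  fit <- minpack.lm::nls.lm(
    start, fn = residuals_,
    control = minpack.lm::nls.lm.control(maxiter = 400))
  if (fit$deviance > 0.01) {
    stop("evoked-shape calibration did not converge", call. = FALSE)
  }
  out <- as_cal(fit$par)
  out$deviance <- fit$deviance
  .calibration_cache[[key]] <- out
  out
}
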