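#' Build the deterministic intensity trace for a session
#'
#' Returns the expected firing intensity (spikes/s per bin) over a whole
#' session: a constant background plus, for each face or scene event, the
#' unit's evoked component (calibrated plateau + onset transient; scenes
#' scaled by `scene_gain`; objects contribute nothing). Spontaneous bursts
#' are added separately by [add_spontaneous_bursts()].
#'
#' @param profile A [unit_profile()].
#' @param events An [event_table()] (may have zero rows for a resting
#'   session).
#' @param duration_s Session duration, s; must cover all events plus the
#'   trial epoch.
#' @param resolution_ms Bin width, ms.
#' @param baseline `"task"` or `"resting"`: which background component of the
#'   profile to use.
#' @param spec A [session_spec()] (supplies the epoch geometry for the
#'   coverage check and the calibration).
#' @return Numeric vector of intensities, one per bin.
#' @export
build_intensity <- function(profile, events, duration_s, resolution_ms = 1,
                            baseline = c("task", "resting"),
                            spec = session_spec()) {
  baseline <- match.arg(baseline)
  res <- resolution_ms
  n <- as.integer(round(duration_s * 1000 / res))
  base <- if (baseline == "task") profile$baseline_rate else profile$rest_rate
  lam <- rep(base, n)
  if (nrow(events) && profile$modulated) {
    if (max(events$onset_s) * 1000 + spec$epoch_trial > duration_s * 1000) {
      stop("duration does not cover all events plus the trial epoch",
           call. = FALSE)
    }
    cal <- calibrate_evoked_shape(profile, spec)
    tt <- seq(0, spec$epoch_trial - res, by = res)
    shape <- evoked_shape(tt, res, cal)
    gains <- c(face = 1, scene = profile$scene_gain, object = 0)
    for (i in seq_len(nrow(events))) {
      g <- gains[[events$category[i]]]
      if (g == 0) next
      i0 <- as.integer(round(events$onset_s[i] * 1000 / res))
      idx <- i0 + seq_along(tt)
      lam[idx] <- lam[idx] + g * shape
    }
  }
  if (any(lam < 0)) stop("profile yields negative intensity", call. = FALSE)
  lam
}

#' Add spontaneous bursts to an intensity trace
#'
#' Burst centres are drawn from a homogeneous Poisson process at
#' `burst_rate` over the active bins; each centre adds a Gaussian intensity
#' bump with the given peak and FWHM (truncated at +/- 4 sigma). The expected
#' added mean rate over an active stretch is
#' `burst_rate * spikes_per_burst(burst_peak_rate, burst_fwhm)`.
#'
#' @param intensity Numeric intensity trace (spikes/s per bin).
#' @param burst_rate Bursts per second.
#' @param burst_peak_rate Peak bump intensity, spikes/s.
#' @param burst_fwhm Bump FWHM, ms.
#' @param resolution_ms Bin width, ms.
#' @param active Logical mask of bins where bursts may occur (default all).
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return The intensity trace with bumps added.
#' @export
add_spontaneous_bursts <- function(intensity, burst_rate, burst_peak_rate,
                                   burst_fwhm, resolution_ms = 1,
                                   active = NULL, seed = NULL) {
  if (burst_rate <= 0 || burst_peak_rate <= 0) return(intensity)
  active <- active %||% rep(TRUE, length(intensity))
  stopifnot(length(active) == length(intensity))
  with_seed(seed, {
    dt <- resolution_ms / 1000
    act_idx <- which(active)
    n_burst <- stats::rpois(1, burst_rate * length(act_idx) * dt)
    if (n_burst > 0) {
      centres <- sample(act_idx, n_burst, replace = TRUE)
      sigma_b <- burst_fwhm * FWHM_TO_SIGMA / resolution_ms # bins
      half <- ceiling(4 * sigma_b)
      off <- seq(-half, half)
      bump <- burst_peak_rate * exp(-off^2 / (2 * sigma_b^2))
      for (c0 in centres) {
        idx <- c0 + off
        ok <- idx >= 1 & idx <= length(intensity)
        intensity[idx[ok]] <- intensity[idx[ok]] + bump[ok]
      }
    }
    intensity
  })
}

#' Sample an inhomogeneous Poisson spike train from an intensity trace
#'
#' Bin counts are Poisson with mean `intensity * dt`; spike times are placed
#' uniformly within their bin, so the train is exact at the stated
#' resolution.
#'
#' @param intensity Non-negative intensity trace (spikes/s per bin).
#' @param resolution_ms Bin width, ms.
#' @param seed Optional integer seed (RNG state restored afterwards).
#' @param session Session label for the resulting train.
#' @return A [spike_train()].
#' @export
sample_poisson_train <- function(intensity, resolution_ms = 1, seed = NULL,
                                 session = "task") {
  stopifnot(all(intensity >= 0))
  with_seed(seed, {
    dt <- resolution_ms / 1000
    counts <- stats::rpois(length(intensity), intensity * dt)
    bins <- rep.int(seq_along(intensity), counts)
    times <- (bins - 1 + stats::runif(length(bins))) * dt
    spike_train(times, duration_s = length(intensity) * dt,
                resolution_ms = resolution_ms, session = session)
  })
}

# Trial category sequence: random permutation at fixed proportions, rotated
# minimally so the first part holds exactly the required number of face
# trials; redrawn in the (rare) case no rotation achieves it.
trial_sequence <- function(spec) {
  cats <- c(rep("face", spec$n_face_trials),
            rep("scene", spec$n_scene_trials),
            rep("object", spec$n_object_trials))
  n <- length(cats)
  iti <- spec$fixation_dur + spec$stimulus_dur
  onsets <- spec$fixation_dur + iti * (seq_len(n) - 1)
  n_part1 <- sum(onsets < spec$part1_dur)
  for (attempt in 1:100) {
    perm <- sample(cats)
    counts <- vapply(0:(n - 1), function(r) {
      sum(perm[(((seq_len(n_part1) - 1) + r) %% n) + 1] == "face")
    }, integer(1))
    hits <- which(counts == spec$n_face_part1) - 1L
    if (length(hits)) {
      r <- hits[which.min(pmin(hits, n - hits))]
      perm <- perm[((seq_len(n) - 1 + r) %% n) + 1]
      return(list(category = perm, onset_s = onsets))
    }
  }
  stop("could not satisfy the part-1 face-trial constraint")
}

#' Generate a complete synthetic two-session study
#'
#' Produces a task session (stimulus train + event table) and a resting
#' session for one unit preset, fully determined by `(preset, seed)`. The
#' trial order is a random permutation at the specified category
#' proportions, rotated so the first part (350 s) contains exactly 70 face
#' trials. Spontaneous bursts are present during resting and inter-stimulus
#' intervals for the bursting presets. Two randomly chosen face trials are
#' flagged as incorrect responses.
#'
#' @param preset Preset name (see [preset_profile()]).
#' @param seed Integer seed; identical `(preset, seed)` give identical
#'   studies.
#' @param spec A [session_spec()].
#' @return A list of class `mua_study` with elements `task`, `events`,
#'   `resting`, `profile`, `preset`, `seed`, `spec`.
#' @export
#' @examples
#' study <- generate_study("ctrl", seed = 1)
#' study$events
generate_study <- function(preset = c("mu1", "mu2", "ctrl", "null"), seed,
                           spec = session_spec()) {
  preset <- match.arg(preset)
  profile <- preset_profile(preset)
  with_seed(seed, {
    seq_ <- trial_sequence(spec)
    n <- length(seq_$category)
    fam <- rep(NA_character_, n)
    for (cat in c("face", "scene")) {
      i <- which(seq_$category == cat)
      fam[i] <- sample(rep(c("familiar", "unfamiliar"), length.out = length(i)))
    }
    correct <- rep(TRUE, n)
    correct[sample(which(seq_$category == "face"), 2)] <- FALSE
    events <- event_table(seq_$onset_s, seq_$category, fam, correct)

    res <- spec$resolution
    lam_task <- build_intensity(profile, events, spec$task_dur, res,
                                baseline = "task", spec = spec)
    stim_on <- rep(FALSE, length(lam_task))
    for (o in events$onset_s) {
      i0 <- as.integer(round(o * 1000 / res))
      stim_on[i0 + seq_len(as.integer(spec$stimulus_dur * 1000 / res))] <- TRUE
    }
    lam_task <- add_spontaneous_bursts(lam_task, profile$burst_rate,
                                       profile$burst_peak_rate,
                                       profile$burst_fwhm, res,
                                       active = !stim_on)
    task <- sample_poisson_train(lam_task, res, session = "task")

    lam_rest <- build_intensity(profile, events[0, ], spec$resting_dur, res,
                                baseline = "resting", spec = spec)
    lam_rest <- add_spontaneous_bursts(lam_rest, profile$burst_rate,
                                       profile$burst_peak_rate,
                                       profile$burst_fwhm, res)
    resting <- sample_poisson_train(lam_rest, res, session = "resting")

    structure(list(task = task, events = events, resting = resting,
                   profile = profile, preset = preset, seed = seed,
                   spec = spec, unit = preset),
              class = "mua_study")
  })
}

#' @export
print.mua_study <- function(x, ...) {
  cat(sprintf(
    "<mua_study '%s' (seed %s): task %d spikes/%d trials, resting %d spikes>\n",
    x$preset, format(x$seed), nrow(x$task), nrow(x$events), nrow(x$resting)))
  invisible(x)
}
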