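#' Assign trials to analysis parts
#'
#' Splits the task session into a first part with duration equal to the
#' resting session and a second (remainder) part, assigning each trial by
#' its onset time: a trial belongs to part 1 iff its onset is before
#' `part1_dur`, even if its epoch crosses the boundary.
#'
#' @param events An [event_table()].
#' @param part1_dur First-part duration, s.
#' @return The event table with an added `part` column
#'   (`"part1"`/`"part2"`).
#' @export
#' @examples
#' ev <- event_table(c(1.2, 3.4, 400), c("face", "scene", "face"))
#' split_parts(ev)
split_parts <- function(events, part1_dur = 350) {
  stopifnot(nrow(events) > 0)
  part <- ifelse(events$onset_s < part1_dur, "part1", "part2")
  if (all(part == "part2")) stop("part 1 is empty", call. = FALSE)
  out <- dplyr::mutate(events, part = part)
  class(out) <- class(events)
  out
}

#' Cut per-trial epochs around stimulus onsets
#'
#' Extracts, for each selected trial, the binarized spike counts over a
#' window of `baseline_ms` before to `trial_ms` after stimulus onset. Bins
#' are half-open `[t, t + resolution)` in ms relative to onset; the onset
#' bin has relative time 0. Trials whose epoch would cross the recording
#' edge are dropped with a warning. Setting `drop_incorrect = TRUE`
#' additionally removes trials flagged as incorrect responses (a robustness
#' variant; the main analysis keeps them).
#'
#' @param train A [spike_train()].
#' @param events An [event_table()], optionally with a `part` column.
#' @param categories Categories to keep (objects are excluded from all
#'   analyses by default).
#' @param part Optional `"part1"`/`"part2"` filter (requires
#'   [split_parts()] first).
#' @param baseline_ms,trial_ms Epoch window, ms.
#' @param drop_incorrect Drop incorrect-response trials.
#' @return An object of class `epoch_set`: per-trial count matrix plus the
#'   retained event rows.
#' @export
cut_epochs <- function(train, events, categories = "face", part = NULL,
                       baseline_ms = 500, trial_ms = 1250,
                       drop_incorrect = FALSE) {
  ev <- dplyr::filter(events, .data$category %in% categories)
  if (!is.null(part)) {
    stopifnot("part" %in% names(ev))
    ev <- dplyr::filter(ev, .data$part == !!part)
  }
  if (drop_incorrect) ev <- dplyr::filter(ev, .data$correct)
  res <- train_resolution(train)
  dur_ms <- train_duration(train) * 1000
  fits <- ev$onset_s * 1000 - baseline_ms >= 0 &
    ev$onset_s * 1000 + trial_ms <= dur_ms
  if (any(!fits)) {
    warning(sprintf("dropping %d trial(s) whose epoch crosses the record edge",
                    sum(!fits)), call. = FALSE)
    ev <- ev[fits, ]
  }
  if (!nrow(ev)) stop("no trials left to epoch", call. = FALSE)
  counts <- bin_spikes(train, res)
  nb <- as.integer((baseline_ms + trial_ms) / res)
  rel_idx <- seq_len(nb) - as.integer(baseline_ms / res) - 1L # bin starts
  mat <- t(vapply(ev$onset_s, function(o) {
    i0 <- as.integer(round(o * 1000 / res))
    counts[i0 + rel_idx + 1L]
  }, integer(nb)))
  structure(list(
    counts = mat,
    rel_time_ms = rel_idx * res,
    events = ev,
    baseline_ms = baseline_ms, trial_ms = trial_ms, resolution_ms = res
  ), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set: %d trials x %d bins ([%d, %d) ms), %d spikes>\n",
              nrow(x$counts), ncol(x$counts), -x$baseline_ms, x$trial_ms,
              sum(x$counts)))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$counts)

#' Number of trials in an epoch set
#' @param x An `epoch_set`.
#' @export
n_trials <- function(x) nrow(x$counts)

#' @describeIn cut_epochs Long-format view of an epoch set: one row per
#'   trial and bin with a non-zero count (plus trial metadata).
#' @param x An `epoch_set`.
#' @param ... Unused.
#' @export
tidy.epoch_set <- function(x, ...) {
  nz <- which(x$counts > 0, arr.ind = TRUE)
  tibble::tibble(
    trial = x$events$trial[nz[, 1]],
    category = x$events$category[nz[, 1]],
    rel_time_ms = x$rel_time_ms[nz[, 2]],
    count = x$counts[nz]
  ) |> dplyr::arrange(.data$trial, .data$rel_time_ms)
}
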