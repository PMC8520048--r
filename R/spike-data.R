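#' Construct a spike train
#'
#' A spike train is a tibble with a single `time_s` column holding ordered
#' spike times (seconds) for one unit over one continuous recording session,
#' carrying the session duration and the binning resolution as attributes.
#' Multiple spikes falling into one bin at the stated resolution are collapsed
#' to the bin count on binarization (see [bin_spikes()]).
#'
#' @param time_s Numeric vector of spike times in seconds, strictly inside
#'   `[0, duration_s]`. Unsorted input is sorted.
#' @param duration_s Session duration in seconds.
#' @param resolution_ms Bin width in milliseconds used when the train is
#'   binarized (default 1 ms).
#' @param session Free-text session label (`"task"` or `"resting"`).
#'
#' @return A tibble of class `spike_train` with column `time_s`.
#' @export
#' @examples
#' st <- spike_train(c(0.1, 0.5, 2.2), duration_s = 10)
#' train_duration(st)
spike_train <- function(time_s, duration_s, resolution_ms = 1,
                        session = "task") {
  stopifnot(is.numeric(time_s), length(duration_s) == 1L, duration_s > 0,
            resolution_ms > 0)
  time_s <- sort(as.numeric(time_s))
  if (length(time_s) && (time_s[1] < 0 || time_s[length(time_s)] > duration_s)) {
    stop("spike times must lie within [0, duration_s]", call. = FALSE)
  }
  out <- tibble::tibble(time_s = time_s)
  attr(out, "duration_s") <- as.numeric(duration_s)
  attr(out, "resolution_ms") <- as.numeric(resolution_ms)
  attr(out, "session") <- session
  class(out) <- c("spike_train", class(out))
  out
}

#' @rdname spike_train
#' @param x A `spike_train`.
#' @export
train_duration <- function(x) attr(x, "duration_s")

#' @rdname spike_train
#' @export
train_resolution <- function(x) attr(x, "resolution_ms")

#' Binarize a spike train
#'
#' Counts spikes in contiguous half-open bins `[t, t + resolution)` covering
#' the whole session.
#'
#' @param train A [spike_train()].
#' @param resolution_ms Bin width in ms; defaults to the train's resolution.
#' @return Integer vector of per-bin spike counts.
#' @export
bin_spikes <- function(train, resolution_ms = NULL) {
  res <- resolution_ms %||% train_resolution(train)
  dt <- res / 1000
  n <- ceiling(train_duration(train) / dt)
  # nanosecond slop so times meant to sit on a bin boundary land in it
  idx <- pmin(floor(train$time_s / dt + 1e-9) + 1L, n)
  counts <- integer(n)
  if (length(idx)) {
    tab <- tabulate(idx, nbins = n)
    counts <- tab
  }
  counts
}

#' Count spikes in half-open windows
#'
#' Number of spikes with `onset <= t < onset + length` for each window onset,
#' computed against the sorted spike times. This is the raw (unsmoothed)
#' spike-count statistic used by the window-ranking analysis.
#'
#' @param times Sorted numeric spike times (seconds).
#' @param onsets_s Window onsets in seconds.
#' @param length_ms Window length in milliseconds (>= one bin).
#' @return Integer vector of counts, one per onset.
#' @keywords internal
count_in_windows <- function(times, onsets_s, length_ms) {
  len_s <- length_ms / 1000
  # findInterval with left.open counts strictly-smaller elements, giving the
  # half-open [onset, onset + length) convention
  hi <- findInterval(onsets_s + len_s, times, left.open = TRUE)
  lo <- findInterval(onsets_s, times, left.open = TRUE)
  as.integer(hi - lo)
}

#' Construct a stimulus event table
#'
#' @param onset_s Stimulus onset times in seconds, strictly increasing.
#' @param category Factor/character: `"face"`, `"scene"` or `"object"`.
#' @param familiarity `"familiar"` or `"unfamiliar"` (`NA` allowed for
#'   objects).
#' @param correct Logical: was the behavioral response correct.
#' @return A tibble of class `event_table`.
#' @export
event_table <- function(onset_s, category,
                        familiarity = NA_character_, correct = TRUE) {
  stopifnot(all(diff(onset_s) > 0))
  category <- as.character(category)
  if (!all(category %in% c("face", "scene", "object"))) {
    stop("category must be face, scene or object", call. = FALSE)
  }
  out <- tibble::tibble(
    trial = seq_along(onset_s),
    onset_s = as.numeric(onset_s),
    category = category,
    familiarity = rep_len(as.character(familiarity), length(onset_s)),
    correct = rep_len(as.logical(correct), length(onset_s))
  )
  class(out) <- c("event_table", class(out))
  out
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train: %d spikes over %.1f s (%s session, %g ms bins)>\n",
              nrow(x), train_duration(x), attr(x, "session"),
              train_resolution(x)))
  NextMethod()
}

# ---- session I/O -----------------------------------------------------------

#' Write a simulated study to disk
#'
#' Spike times go to two-column CSVs (`time_s`, `unit`), events to a CSV, and
#' durations/resolution/preset to a JSON sidecar, so a study round-trips
#' through plain text.
#'
#' @param study An object returned by [generate_study()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "mua_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(
    tibble::tibble(time_s = study$task$time_s, unit = study$unit),
    file.path(dir, "task_spikes.csv"))
  readr::write_csv(
    tibble::tibble(time_s = study$resting$time_s, unit = study$unit),
    file.path(dir, "resting_spikes.csv"))
  readr::write_csv(study$events, file.path(dir, "events.csv"))
  meta <- list(
    unit = study$unit,
    preset = study$preset,
    seed = study$seed,
    task_duration_s = train_duration(study$task),
    resting_duration_s = train_duration(study$resting),
    resolution_ms = train_resolution(study$task)
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a study written by [write_study()]
#'
#' @param dir Directory containing `task_spikes.csv`, `resting_spikes.csv`,
#'   `events.csv` and `meta.json`.
#' @return An object of class `mua_study`.
#' @export
read_study <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  task <- readr::read_csv(file.path(dir, "task_spikes.csv"),
                          show_col_types = FALSE)
  rest <- readr::read_csv(file.path(dir, "resting_spikes.csv"),
                          show_col_types = FALSE)
  ev <- readr::read_csv(file.path(dir, "events.csv"), show_col_types = FALSE)
  events <- event_table(ev$onset_s, ev$category, ev$familiarity, ev$correct)
  structure(list(
    task = spike_train(task$time_s, meta$task_duration_s, meta$resolution_ms,
                       session = "task"),
    resting = spike_train(rest$time_s, meta$resting_duration_s,
                          meta$resolution_ms, session = "resting"),
    events = events,
    unit = meta$unit,
    preset = meta$preset,
    seed = meta$seed
  ), class = "mua_study")
}
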