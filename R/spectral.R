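#' Select 500 ms segments for spectral analysis
#'
#' Segment onsets per condition: faces segments start at the unit's peak
#' modulation time (estimated on independent data) within each face trial;
#' prestimulus segments span the 500 ms baseline before each onset; resting
#' segments start at uniformly random positions that keep the whole segment
#' inside the record.
#'
#' @param events Event table (typically the part-1 rows), used for faces and
#'   prestimulus onsets.
#' @param resting A resting [spike_train()].
#' @param peak_ms Peak-modulation time, ms after stimulus onset.
#' @param n_resting Number of resting segments (defaults to the number of
#'   face trials in `events`).
#' @param segment_ms Segment duration, ms.
#' @param seed Optional seed for the resting draw.
#' @return A tibble with columns `condition` (`faces`, `prestimulus`,
#'   `resting`) and `start_s`.
#' @export
select_segments <- function(events, resting, peak_ms, n_resting = NULL,
                            segment_ms = 500, seed = NULL) {
  faces <- events$onset_s[events$category == "face"]
  n_resting <- n_resting %||% length(faces)
  seg_s <- segment_ms / 1000
  rest_max <- train_duration(resting) - seg_s
  stopifnot(rest_max > 0)
  starts_rest <- with_seed(seed, stats::runif(n_resting, 0, rest_max))
  dplyr::bind_rows(
    tibble::tibble(condition = "faces", start_s = faces + peak_ms / 1000),
    tibble::tibble(condition = "prestimulus", start_s = faces - seg_s),
    tibble::tibble(condition = "resting", start_s = starts_rest)
  )
}

#' Power spectral density of spike-train segments
#'
#' For each segment the binarized (binary, unsmoothed) spike train is
#' mean-subtracted and Fourier transformed; power is `|X|^2 / (N * dt)`,
#' reported for positive frequencies up to the Nyquist rate. With this
#' normalization a homogeneous Poisson train of intensity `lambda` has a
#' flat expected spectrum at `lambda` for all positive frequencies, and
#' summed power times the frequency step recovers the segment variance
#' (Parseval). 500 ms segments at 1 ms bins give 2 Hz frequency spacing.
#'
#' @param train A [spike_train()].
#' @param starts_s Segment start times, s; segments extending past the
#'   record are dropped with a warning.
#' @param segment_ms Segment duration, ms.
#' @param input `"binary"` (default) transforms the raw binned train;
#'   `"smoothed"` transforms the kernel-smoothed rate instead (which
#'   imposes the kernel's own spectrum; provided for comparison).
#' @param fwhm_ms Kernel width when `input = "smoothed"`.
#' @return A list of class `psd_set`: `freq_hz`, `power` (segments x
#'   frequencies matrix).
#' @export
psd_segments <- function(train, starts_s, segment_ms = 500,
                         input = c("binary", "smoothed"), fwhm_ms = 80) {
  input <- match.arg(input)
  res <- train_resolution(train)
  dt <- res / 1000
  nb <- as.integer(round(segment_ms / res))
  ok <- starts_s >= 0 & starts_s + segment_ms / 1000 <= train_duration(train)
  if (any(!ok)) {
    warning(sprintf("dropping %d segment(s) outside the record", sum(!ok)),
            call. = FALSE)
    starts_s <- starts_s[ok]
  }
  stopifnot(length(starts_s) > 0)
  counts <- bin_spikes(train)
  series <- if (input == "smoothed") {
    smooth_rate(as.numeric(counts), fwhm_ms, res)
  } else counts
  nf <- nb %/% 2
  power <- t(vapply(starts_s, function(s0) {
    i0 <- as.integer(round(s0 * 1000 / res))
    x <- as.numeric(series[i0 + seq_len(nb)])
    x <- x - mean(x)
    X <- stats::fft(x)
    (Mod(X)^2 / (nb * dt))[2:(nf + 1)]
  }, numeric(nf)))
  structure(list(
    freq_hz = seq_len(nf) / (nb * dt),
    power = power,
    input = input, segment_ms = segment_ms
  ), class = "psd_set")
}

#' Condition-averaged power spectra
#'
#' Computes the per-trial power spectrum for each condition's segments
#' (faces and prestimulus from the task train, resting from the resting
#' train) and averages within condition.
#'
#' @param task,resting Task and resting [spike_train()]s.
#' @param segments Segment table from [select_segments()].
#' @param ... Passed to [psd_segments()] (e.g. `input`).
#' @return A tibble of class `psd_result`: `condition`, `freq_hz`,
#'   `mean_power`, `sem`, `n_segments`.
#' @export
condition_psd <- function(task, resting, segments, ...) {
  out <- dplyr::group_by(segments, .data$condition) |>
    dplyr::group_modify(function(d, key) {
      train <- if (key$condition == "resting") resting else task
      ps <- psd_segments(train, d$start_s, ...)
      tibble::tibble(
        freq_hz = ps$freq_hz,
        mean_power = colMeans(ps$power),
        sem = apply(ps$power, 2, stats::sd) / sqrt(nrow(ps$power)),
        n_segments = nrow(ps$power)
      )
    }) |>
    dplyr::ungroup()
  class(out) <- c("psd_result", class(out))
  out
}
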