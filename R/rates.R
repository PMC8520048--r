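#' Instantaneous firing rate by Gaussian-kernel smoothing
#'
#' Convolves the binarized spike train (spikes per bin divided by the bin
#' width, i.e. spikes/s) with a unit-area Gaussian kernel of the given full
#' width at half maximum (sigma = FWHM / 2.3548). Convolution is zero-padded,
#' so rates within ~4 sigma of the record edges are deflated; session-level
#' summaries exclude a 2 sigma margin by default (see
#' [condition_mean_rate()]).
#'
#' @param x A [spike_train()], an `epoch_set`, or a numeric vector of per-bin
#'   spike counts.
#' @param fwhm_ms Kernel full width at half maximum, ms (default 80).
#' @param ... Passed between methods.
#' @return For a spike train: a tibble of class `rate_trace` with columns
#'   `time_s` (bin start) and `rate` (spikes/s). For an epoch set: an
#'   `epoch_rates` object holding a trials-by-bins rate matrix. For a
#'   numeric vector: the smoothed rate vector.
#' @export
#' @examples
#' st <- spike_train(c(0.5, 0.52, 1.4), duration_s = 2)
#' head(smooth_rate(st))
smooth_rate <- function(x, fwhm_ms = 80, ...) UseMethod("smooth_rate")

#' @rdname smooth_rate
#' @param resolution_ms Bin width for the numeric-vector method, ms.
#' @export
smooth_rate.numeric <- function(x, fwhm_ms = 80, resolution_ms = 1, ...) {
  w <- gaussian_kernel(fwhm_ms, resolution_ms)
  conv_same(x, w) * 1000 / resolution_ms
}

#' @rdname smooth_rate
#' @export
smooth_rate.spike_train <- function(x, fwhm_ms = 80, ...) {
  res <- train_resolution(x)
  counts <- bin_spikes(x)
  rate <- smooth_rate(as.numeric(counts), fwhm_ms, res)
  sigma_bins <- fwhm_ms * FWHM_TO_SIGMA / res
  out <- tibble::tibble(
    time_s = (seq_along(rate) - 1) * res / 1000,
    rate = rate
  )
  attr(out, "resolution_ms") <- res
  attr(out, "fwhm_ms") <- fwhm_ms
  attr(out, "edge_bins") <- ceiling(2 * sigma_bins)
  class(out) <- c("rate_trace", class(out))
  out
}

#' @rdname smooth_rate
#' @export
smooth_rate.epoch_set <- function(x, fwhm_ms = 80, ...) {
  w <- gaussian_kernel(fwhm_ms, x$resolution_ms)
  rates <- t(apply(x$counts, 1, function(row) conv_same(row, w))) *
    1000 / x$resolution_ms
  structure(list(
    rates = rates,
    rel_time_ms = x$rel_time_ms,
    events = x$events,
    baseline_ms = x$baseline_ms, trial_ms = x$trial_ms,
    resolution_ms = x$resolution_ms, fwhm_ms = fwhm_ms
  ), class = "epoch_rates")
}

#' @export
print.epoch_rates <- function(x, ...) {
  cat(sprintf(
    "<epoch_rates: %d trials x %d bins, FWHM %g ms>\n",
    nrow(x$rates), ncol(x$rates), x$fwhm_ms))
  invisible(x)
}

# Pool instantaneous-rate samples from the supported containers.
pool_rate_samples <- function(x, period_ms = NULL, exclude_edges = TRUE) {
  if (inherits(x, "epoch_rates")) {
    cols <- if (is.null(period_ms)) seq_along(x$rel_time_ms) else {
      which(x$rel_time_ms >= period_ms[1] & x$rel_time_ms <= period_ms[2])
    }
    if (!length(cols)) stop("empty period", call. = FALSE)
    as.numeric(x$rates[, cols])
  } else if (inherits(x, "rate_trace")) {
    v <- x$rate
    if (exclude_edges) {
      eb <- attr(x, "edge_bins")
      if (!is.null(period_ms)) {
        keep <- x$time_s * 1000 >= period_ms[1] & x$time_s * 1000 <= period_ms[2]
        v <- v[keep]
      } else if (length(v) > 2 * eb) {
        v <- v[(eb + 1):(length(v) - eb)]
      }
    }
    v
  } else if (is.numeric(x)) {
    as.numeric(x)
  } else {
    stop("unsupported input for rate pooling", call. = FALSE)
  }
}

#' Mean and SEM of pooled instantaneous firing rates
#'
#' Pools all instantaneous-rate samples (across trials for epoch rates, or
#' across the session for a rate trace, excluding a 2 sigma edge margin)
#' and reports their mean and the pooled-sample SEM
#' (`sd / sqrt(n_samples)`). Note the pooled samples are autocorrelated over
#' the kernel width, so this SEM describes the sample spread convention used
#' for reporting, not the sampling error of the mean as an estimate of the
#' underlying intensity (see the methods vignette).
#'
#' @param x An `epoch_rates` object, a `rate_trace`, or a numeric vector of
#'   rate samples.
#' @param period_ms Optional `c(t0, t1)` window in ms (relative to stimulus
#'   onset for epochs, absolute for traces) over which to pool.
#' @return A one-row tibble with `mean_rate`, `sem`, `n_samples`.
#' @export
condition_mean_rate <- function(x, period_ms = NULL) {
  v <- pool_rate_samples(x, period_ms)
  if (!length(v)) stop("empty period", call. = FALSE)
  tibble::tibble(
    mean_rate = mean(v),
    sem = stats::sd(v) / sqrt(length(v)),
    n_samples = length(v)
  )
}

#' Normalized distribution of instantaneous firing rates
#'
#' Histogram of pooled rate samples in fixed-width bins from 0 to a display
#' limit, normalized by the total number of samples; the fraction of samples
#' beyond the limit is reported separately, so relative frequencies plus the
#' tail fraction sum to one.
#'
#' @param x Input accepted by [condition_mean_rate()].
#' @param bin_width Bin width in spikes/s.
#' @param limit Display limit in spikes/s; mass beyond it goes to
#'   `tail_fraction`.
#' @param period_ms Optional pooling window, ms.
#' @return A tibble of class `rate_histogram` with columns `bin_lo`,
#'   `bin_hi`, `rel_freq`, and attribute `tail_fraction`.
#' @export
rate_histogram <- function(x, bin_width = 1, limit = 100, period_ms = NULL) {
  stopifnot(bin_width > 0)
  v <- pool_rate_samples(x, period_ms)
  edges <- seq(0, limit, by = bin_width)
  idx <- findInterval(v, edges, rightmost.closed = FALSE)
  inside <- idx >= 1 & v < limit
  freq <- tabulate(idx[inside], nbins = length(edges) - 1)
  out <- tibble::tibble(
    bin_lo = edges[-length(edges)],
    bin_hi = edges[-1],
    rel_freq = freq / length(v)
  )
  attr(out, "tail_fraction") <- sum(!inside) / length(v)
  attr(out, "n_samples") <- length(v)
  class(out) <- c("rate_histogram", class(out))
  out
}

#' @describeIn rate_histogram Tail fraction beyond the display limit.
#' @export
tail_fraction <- function(x) attr(x, "tail_fraction")
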