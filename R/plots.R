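#' Plot methods
#'
#' `autoplot()` methods render each result type as a ggplot: the per-bin
#' t-trace with shaded significant clusters for a `modulation_result`,
#' condition spectra with SEM ribbons for a `psd_result`, and the
#' percentage of spontaneous windows against window length (one line per
#' threshold) for a `window_curve`.
#'
#' @param object The result object.
#' @param alpha Cluster significance level used for shading.
#' @param ... Unused.
#' @return A ggplot object.
#' @name evospike-plots
NULL

#' @rdname evospike-plots
#' @export
autoplot.modulation_result <- function(object, alpha = 0.05, ...) {
  sig <- object$clusters[object$clusters$p < alpha, , drop = FALSE]
  p <- ggplot2::ggplot(object$t, ggplot2::aes(x = .data$time_ms,
                                              y = .data$t)) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$t_crit,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from stimulus onset (ms)", y = "t statistic",
                  title = sprintf("Cluster-permutation scan (%s)",
                                  object$contrast)) +
    ggplot2::theme_minimal()
  if (nrow(sig)) {
    p <- p + ggplot2::annotate("rect", xmin = sig$start_ms,
                               xmax = sig$end_ms, ymin = -Inf, ymax = Inf,
                               alpha = 0.15, fill = "red")
  }
  p
}

#' @rdname evospike-plots
#' @export
autoplot.psd_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$freq_hz,
                                       y = .data$mean_power,
                                       colour = .data$condition,
                                       fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_power - .data$sem,
                                      ymax = .data$mean_power + .data$sem),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "power",
                  title = "Condition-averaged power spectra") +
    ggplot2::theme_minimal()
}

#' @rdname evospike-plots
#' @export
autoplot.window_curve <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$length_ms,
                               y = .data$pct_spontaneous,
                               colour = factor(.data$threshold))) +
    ggplot2::geom_hline(yintercept = 50, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_colour_discrete(name = "top fraction",
                                   labels = function(x) {
                                     paste0(100 * as.numeric(x), "%")
                                   }) +
    ggplot2::labs(
      x = "window length (ms)",
      y = "% spontaneous windows among top-ranked",
      title = sprintf("Window ranking vs %s activity",
                      attr(object, "comparison"))) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' @rdname evospike-plots
#' @param x A `rate_histogram` or the stacked histogram tibble from a
#'   results bundle (with a `condition` column).
#' @export
plot_rate_histograms <- function(x, ...) {
  d <- tibble::as_tibble(x)
  if (!"condition" %in% names(d)) d$condition <- "rates"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_lo, y = .data$rel_freq,
                                  fill = .data$condition)) +
    ggplot2::geom_col(position = "identity", alpha = 0.5, width = 1) +
    ggplot2::labs(x = "instantaneous firing rate (spikes/s)",
                  y = "relative frequency",
                  title = "Distribution of instantaneous firing rates") +
    ggplot2::theme_minimal()
}

#' @rdname evospike-plots
#' @export
autoplot.rate_histogram <- function(object, ...) plot_rate_histograms(object)

#' Raster and instantaneous-rate view of a session excerpt
#'
#' Shows the smoothed instantaneous firing rate over a time window with a
#' spike raster underneath, optionally marking stimulus-on intervals.
#'
#' @param train A [spike_train()].
#' @param from_s,to_s Excerpt bounds, s.
#' @param events Optional [event_table()]; stimulus periods are shaded.
#' @param fwhm_ms Kernel width, ms.
#' @param stimulus_dur_s Stimulus duration used for shading, s.
#' @return A ggplot object.
#' @export
plot_raster_rate <- function(train, from_s = 0, to_s = 30, events = NULL,
                             fwhm_ms = 80, stimulus_dur_s = 1) {
  trace <- smooth_rate(train, fwhm_ms)
  trace <- trace[trace$time_s >= from_s & trace$time_s <= to_s, ]
  spikes <- train$time_s[train$time_s >= from_s & train$time_s <= to_s]
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$time_s,
                                           y = .data$rate)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_rug(data = tibble::tibble(time_s = spikes),
                      ggplot2::aes(x = .data$time_s), inherit.aes = FALSE,
                      sides = "b", length = ggplot2::unit(0.04, "npc")) +
    ggplot2::labs(x = "time (s)", y = "instantaneous rate (spikes/s)") +
    ggplot2::theme_minimal()
  if (!is.null(events)) {
    on <- events$onset_s[events$onset_s >= from_s & events$onset_s <= to_s]
    if (length(on)) {
      p <- p + ggplot2::annotate("rect", xmin = on,
                                 xmax = on + stimulus_dur_s,
                                 ymin = -Inf, ymax = Inf, alpha = 0.1,
                                 fill = "red")
    }
  }
  p
}
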