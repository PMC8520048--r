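#' Analysis configuration
#'
#' Collects every tunable parameter of the pipeline in one serializable
#' list, so a run is reproducible from the configuration and seed alone.
#'
#' @param preset Generator preset, or `NA` when analyzing data read from
#'   disk.
#' @param seed Integer seed controlling the generator, the permutation
#'   tests, the resting segment draw and the window bootstrap.
#' @param fwhm_ms Smoothing kernel FWHM, ms.
#' @param alpha_cluster Cluster-forming two-tailed alpha.
#' @param n_perm Permutations for the cluster tests.
#' @param lengths_ms,thresholds Window-ranking grid.
#' @param n_boot Bootstrap draws for resting windows.
#' @param psd_input `"binary"` or `"smoothed"` spectral input.
#' @param hist_bin,hist_limit Rate-histogram bin width and display limit,
#'   spikes/s.
#' @param drop_incorrect Exclude incorrect-response trials.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(preset = "mu1", seed = 1, fwhm_ms = 80,
                            alpha_cluster = 0.05, n_perm = 1000,
                            lengths_ms = c(2, 5, 10, 20, 50, 100, 150, 200,
                                           250),
                            thresholds = c(0.05, 0.2, 0.35, 0.5),
                            n_boot = 1000,
                            psd_input = c("binary", "smoothed"),
                            hist_bin = 1, hist_limit = 100,
                            drop_incorrect = FALSE) {
  structure(list(
    preset = preset, seed = seed, fwhm_ms = fwhm_ms,
    alpha_cluster = alpha_cluster, n_perm = n_perm,
    lengths_ms = lengths_ms, thresholds = thresholds, n_boot = n_boot,
    psd_input = match.arg(psd_input), hist_bin = hist_bin,
    hist_limit = hist_limit, drop_incorrect = drop_incorrect
  ), class = "analysis_config")
}

#' Simulate a study and write it to disk
#'
#' @param config An [analysis_config()] with a valid `preset`.
#' @param dir Output directory.
#' @return The study, invisibly; files are written via [write_study()].
#' @export
run_simulate <- function(config, dir) {
  study <- generate_study(config$preset, config$seed)
  write_study(study, dir)
  jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(study)
}

#' Run the full comparison analysis on a study
#'
#' Orchestrates the stages in their dependency order. Part 2 of the task
#' session (independent data) establishes face selectivity and the
#' modulation period and peak; part 1 supplies every evoked-versus-
#' spontaneous comparison: condition mean rates, rate histograms, per-trial
#' power spectra, and the window-ranking curves against resting and
#' prestimulus activity. If no significant modulation is found (control
#' units), the peak of the raw t-trace is used to align windows and the
#' period-dependent tables are still produced.
#'
#' @param study An `mua_study` (from [generate_study()] or [read_study()]).
#' @param config An [analysis_config()].
#' @return A list of class `mua_results` with elements `modulation`,
#'   `selectivity`, `period`, `condition_means`, `histograms`, `psd`,
#'   `window_resting`, `window_prestimulus`, `config`.
#' @export
run_analysis <- function(study, config = analysis_config()) {
  events <- split_parts(study$events)
  seeds <- derive_seeds(config$seed)

  # part 2: selectivity and modulation period on independent data
  ep2_faces <- cut_epochs(study$task, events, "face", part = "part2",
                          drop_incorrect = config$drop_incorrect)
  ep2_scenes <- cut_epochs(study$task, events, "scene", part = "part2")
  modulation <- cluster_test_vs_baseline(
    ep2_faces, config$fwhm_ms, config$alpha_cluster, config$n_perm,
    seed = seeds["modulation"])
  selectivity <- cluster_test_between(
    ep2_faces, ep2_scenes, config$fwhm_ms, config$alpha_cluster,
    config$n_perm, seed = seeds["selectivity"])
  period <- modulation_period(modulation)
  peak <- if (period$modulated) period$peak_ms else modulation$peak_time_raw
  # the alignment point must leave room for the longest ranking window
  peak <- max(0, min(peak, ep2_faces$trial_ms - max(config$lengths_ms)))
  mod_window <- if (period$modulated) {
    c(period$onset_ms, period$offset_ms)
  } else c(0, 1000)

  # part 1: evoked vs spontaneous comparisons
  ep1_faces <- cut_epochs(study$task, events, "face", part = "part1",
                          drop_incorrect = config$drop_incorrect)
  rates1 <- smooth_rate(ep1_faces, config$fwhm_ms)
  rest_trace <- smooth_rate(study$resting, config$fwhm_ms)
  cm <- dplyr::bind_rows(
    faces = condition_mean_rate(rates1, mod_window),
    prestimulus = condition_mean_rate(rates1, c(-ep1_faces$baseline_ms, -1)),
    resting = condition_mean_rate(rest_trace),
    .id = "condition")
  hist_one <- function(x, period = NULL) {
    h <- rate_histogram(x, config$hist_bin, config$hist_limit, period)
    dplyr::mutate(tibble::as_tibble(h), tail_fraction = tail_fraction(h))
  }
  hists <- dplyr::bind_rows(
    faces = hist_one(rates1, mod_window),
    prestimulus = hist_one(rates1, c(-ep1_faces$baseline_ms, -1)),
    resting = hist_one(rest_trace),
    .id = "condition")
  segs <- select_segments(events[events$part == "part1", ], study$resting,
                          peak, seed = seeds["segments"])
  psd <- condition_psd(study$task, study$resting, segs,
                       input = config$psd_input, fwhm_ms = config$fwhm_ms)
  win_rest <- window_curve(ep1_faces, study$resting, peak,
                           config$lengths_ms, config$thresholds,
                           config$n_boot, seed = seeds["windows"])
  win_pre <- window_curve(ep1_faces, NULL, peak, config$lengths_ms,
                          config$thresholds, comparison = "prestimulus")

  structure(list(
    modulation = modulation, selectivity = selectivity, period = period,
    condition_means = cm, histograms = hists, psd = psd,
    window_resting = win_rest, window_prestimulus = win_pre,
    config = config, preset = study$preset, seed = study$seed
  ), class = "mua_results")
}

# Independent sub-seeds for the stochastic stages, derived from the master
# seed so one integer reproduces the whole run (kept below 2^31).
derive_seeds <- function(seed) {
  base <- (as.numeric(seed) * 48271) %% 2147483399
  s <- (base + c(1, 2, 3, 4) * 7919) %% 2147483399
  names(s) <- c("modulation", "selectivity", "segments", "windows")
  s
}

#' @export
print.mua_results <- function(x, ...) {
  cat(sprintf("<mua_results: preset '%s', seed %s>\n", x$preset,
              format(x$seed)))
  if (x$period$modulated) {
    cat(sprintf("  modulation period [%g, %g] ms, peak %g ms (p = %.4g)\n",
                x$period$onset_ms, x$period$offset_ms, x$period$peak_ms,
                x$period$p))
  } else {
    cat("  no significant modulation\n")
  }
  print(x$condition_means)
  invisible(x)
}

#' Write an analysis results bundle as tidy CSV tables plus a JSON summary
#'
#' @param results An `mua_results` from [run_analysis()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_results_bundle <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, name) readr::write_csv(x, file.path(dir, name))
  w(tidy(results$modulation), "modulation_clusters.csv")
  w(tidy(results$selectivity), "selectivity_clusters.csv")
  w(results$period, "modulation_period.csv")
  w(results$condition_means, "condition_means.csv")
  w(results$histograms, "rate_histograms.csv")
  w(results$psd, "power_spectra.csv")
  w(tidy(results$window_resting), "window_curve_resting.csv")
  w(tidy(results$window_prestimulus), "window_curve_prestimulus.csv")
  summary <- list(
    preset = results$preset, seed = results$seed,
    config = unclass(results$config),
    period = as.list(results$period),
    condition_means = results$condition_means,
    modulated = results$period$modulated
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Render the standard report figures for a results bundle
#'
#' Writes one PNG per result type (modulation t-trace, rate histograms,
#' power spectra, window-ranking curves), each regenerated from the result
#' tables alone.
#'
#' @param results An `mua_results`.
#' @param dir Output directory.
#' @param width,height,dpi Device settings passed to [ggplot2::ggsave()].
#' @return Character vector of files written, invisibly.
#' @export
report_figures <- function(results, dir, width = 7, height = 4.5, dpi = 150) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  figs <- list(
    modulation = autoplot(results$modulation),
    selectivity = autoplot(results$selectivity),
    histograms = plot_rate_histograms(results$histograms),
    psd = autoplot(results$psd),
    window_resting = autoplot(results$window_resting),
    window_prestimulus = autoplot(results$window_prestimulus)
  )
  paths <- file.path(dir, paste0(names(figs), ".png"))
  purrr::walk2(figs, paths, function(p, f) {
    ggplot2::ggsave(f, p, width = width, height = height, dpi = dpi)
  })
  invisible(paths)
}

#' Simulate, analyze and report in one call
#'
#' @param config An [analysis_config()].
#' @param dir Output directory; the dataset goes to `dir/dataset`, tables to
#'   `dir/tables`, figures to `dir/figures`.
#' @param figures Render PNG figures as well.
#' @return The `mua_results`, invisibly.
#' @export
run_study <- function(config = analysis_config(), dir, figures = TRUE) {
  study <- run_simulate(config, file.path(dir, "dataset"))
  results <- run_analysis(study, config)
  write_results_bundle(results, file.path(dir, "tables"))
  if (figures) report_figures(results, file.path(dir, "figures"))
  invisible(results)
}
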