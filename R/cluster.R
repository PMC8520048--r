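# Contiguous supra-threshold clusters of a t-trace restricted to the trial
# period. Clusters are sign-homogeneous runs of |t| > crit scored by summed t.
cluster_masses <- function(tvec, crit) {
  lab <- (tvec > crit) - (tvec < -crit)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  cs <- c(0, cumsum(tvec))
  list(start = starts[keep], end = ends[keep],
       mass = cs[ends[keep] + 1L] - cs[starts[keep]])
}

max_cluster_mass <- function(tvec, crit) {
  cl <- cluster_masses(tvec, crit)
  if (!length(cl$mass)) 0 else max(abs(cl$mass))
}

# One-sample t per column; zero-variance columns give t = 0.
col_t_onesample <- function(X) {
  n <- nrow(X)
  m <- colMeans(X)
  v <- (colSums(X^2) - n * m^2) / (n - 1)
  v[v < .Machine$double.eps] <- Inf
  m / sqrt(v / n)
}

new_modulation_result <- function(clusters, t_tbl, contrast, alpha_cluster,
                                  n_perm, n_trials, t_crit, alpha = 0.05) {
  sig <- clusters[clusters$p < alpha, , drop = FALSE]
  peak_raw <- t_tbl$time_ms[which.max(abs(t_tbl$t))]
  peak <- NA_real_
  if (nrow(sig)) {
    big <- sig[which.max(abs(sig$mass)), ]
    inwin <- t_tbl$time_ms >= big$start_ms & t_tbl$time_ms <= big$end_ms
    peak <- t_tbl$time_ms[inwin][which.max(abs(t_tbl$t[inwin]))]
  }
  structure(list(
    clusters = clusters, t = t_tbl, contrast = contrast,
    peak_time = peak, peak_time_raw = peak_raw,
    alpha_cluster = alpha_cluster, n_perm = n_perm, n_trials = n_trials,
    t_crit = t_crit
  ), class = "modulation_result")
}

# Shared post-processing: observed clusters + permutation null of max mass.
finish_cluster_test <- function(t_obs, time_ms, null_max, crit, contrast,
                                alpha_cluster, n_perm, n_trials) {
  cl <- cluster_masses(t_obs, crit)
  p <- vapply(cl$mass %||% numeric(0), function(m) {
    (1 + sum(null_max >= abs(m))) / (length(null_max) + 1)
  }, numeric(1))
  clusters <- tibble::tibble(
    start_ms = time_ms[cl$start],
    end_ms = time_ms[cl$end],
    mass = cl$mass,
    p = p
  )
  t_tbl <- tibble::tibble(time_ms = time_ms, t = t_obs)
  new_modulation_result(clusters, t_tbl, contrast, alpha_cluster, n_perm,
                        n_trials, crit)
}

#' Cluster-based permutation test of evoked modulation versus baseline
#'
#' Smooths each trial's epoch with a Gaussian kernel, subtracts that trial's
#' mean baseline rate (the 500 ms before onset), computes a per-bin
#' one-sample t across trials over the trial period, forms contiguous
#' clusters of bins exceeding the two-tailed cluster-forming threshold, and
#' scores each cluster by its summed t. Significance is assessed against the
#' permutation distribution of the maximal absolute cluster mass under
#' random sign-flipping of trial traces.
#'
#' @param epochs An `epoch_set` (spike counts; smoothing is applied
#'   internally) or an `epoch_rates` object.
#' @param fwhm_ms Smoothing kernel FWHM, ms (ignored for pre-smoothed
#'   input).
#' @param alpha_cluster Two-tailed cluster-forming alpha (threshold
#'   `qt(1 - alpha/2, n - 1)`).
#' @param n_perm Number of sign-flip permutations.
#' @param seed Optional seed for the permutation draw.
#' @return A `modulation_result`: cluster table (`start_ms`, `end_ms`,
#'   summed-t `mass`, permutation `p`), the per-bin t-trace, and the peak
#'   time (bin of maximal |t| within the largest significant cluster).
#' @export
cluster_test_vs_baseline <- function(epochs, fwhm_ms = 80,
                                     alpha_cluster = 0.05, n_perm = 1000,
                                     seed = NULL) {
  er <- if (inherits(epochs, "epoch_rates")) epochs else {
    smooth_rate(epochs, fwhm_ms)
  }
  n <- nrow(er$rates)
  stopifnot(n >= 2)
  base_cols <- which(er$rel_time_ms < 0)
  trial_cols <- which(er$rel_time_ms >= 0)
  stopifnot(length(base_cols) > 0)
  X <- er$rates[, trial_cols, drop = FALSE] -
    rowMeans(er$rates[, base_cols, drop = FALSE])
  crit <- stats::qt(1 - alpha_cluster / 2, df = n - 1)
  t_obs <- col_t_onesample(X)
  ssq <- colSums(X^2)
  null_max <- with_seed(seed, {
    S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    M <- (S %*% X) / n
    V <- sweep(-n * M^2, 2, ssq, "+") / (n - 1)
    V[V < .Machine$double.eps] <- Inf
    Tm <- M / sqrt(V / n)
    apply(Tm, 1, max_cluster_mass, crit = crit)
  })
  finish_cluster_test(t_obs, er$rel_time_ms[trial_cols], null_max, crit,
                      "vs_baseline", alpha_cluster, n_perm, n)
}

#' Cluster-based permutation test between two conditions
#'
#' Per-bin two-sample (pooled-variance) t between two sets of baseline-
#' corrected smoothed epochs, with the permutation null formed by shuffling
#' condition labels. Cluster formation and scoring as in
#' [cluster_test_vs_baseline()].
#'
#' @param epochs_a,epochs_b `epoch_set` or `epoch_rates` for the two
#'   conditions (e.g. faces and scenes).
#' @inheritParams cluster_test_vs_baseline
#' @return A `modulation_result` with contrast `"between"`; positive mass
#'   means condition A above condition B.
#' @export
cluster_test_between <- function(epochs_a, epochs_b, fwhm_ms = 80,
                                 alpha_cluster = 0.05, n_perm = 1000,
                                 seed = NULL) {
  sm <- function(e) if (inherits(e, "epoch_rates")) e else smooth_rate(e, fwhm_ms)
  ea <- sm(epochs_a); eb <- sm(epochs_b)
  stopifnot(identical(ea$rel_time_ms, eb$rel_time_ms))
  base_cols <- which(ea$rel_time_ms < 0)
  trial_cols <- which(ea$rel_time_ms >= 0)
  bc <- function(e) e$rates[, trial_cols, drop = FALSE] -
    rowMeans(e$rates[, base_cols, drop = FALSE])
  X <- rbind(bc(ea), bc(eb))
  n1 <- nrow(ea$rates); n2 <- nrow(eb$rates); n <- n1 + n2
  stopifnot(n1 >= 2, n2 >= 2)
  crit <- stats::qt(1 - alpha_cluster / 2, df = n - 2)
  two_sample_t <- function(grp1) {
    A <- X[grp1, , drop = FALSE]; B <- X[!grp1, , drop = FALSE]
    m1 <- colMeans(A); m2 <- colMeans(B)
    ss <- (colSums(A^2) - n1 * m1^2) + (colSums(B^2) - n2 * m2^2)
    v <- ss / (n - 2) * (1 / n1 + 1 / n2)
    v[v < .Machine$double.eps] <- Inf
    (m1 - m2) / sqrt(v)
  }
  grp_obs <- c(rep(TRUE, n1), rep(FALSE, n2))
  t_obs <- two_sample_t(grp_obs)
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      g <- logical(n); g[sample.int(n, n1)] <- TRUE
      max_cluster_mass(two_sample_t(g), crit)
    }, numeric(1))
  })
  finish_cluster_test(t_obs, ea$rel_time_ms[trial_cols], null_max, crit,
                      "between", alpha_cluster, n_perm, n)
}

#' Boundaries and peak of the detected modulation period
#'
#' Reports the onset, peak and offset (ms after stimulus onset) of the
#' largest-mass significant cluster; the peak is the bin of maximal |t|
#' within that cluster. With no significant cluster, all three are `NA`
#' ("no modulation").
#'
#' @param result A `modulation_result`.
#' @param alpha Significance level for clusters.
#' @return A one-row tibble with `onset_ms`, `peak_ms`, `offset_ms`,
#'   `p`, `modulated`.
#' @export
modulation_period <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "modulation_result"))
  sig <- result$clusters[result$clusters$p < alpha, , drop = FALSE]
  if (!nrow(sig)) {
    return(tibble::tibble(onset_ms = NA_real_, peak_ms = NA_real_,
                          offset_ms = NA_real_, p = NA_real_,
                          modulated = FALSE))
  }
  big <- sig[which.max(abs(sig$mass)), ]
  inwin <- result$t$time_ms >= big$start_ms & result$t$time_ms <= big$end_ms
  peak <- result$t$time_ms[inwin][which.max(abs(result$t$t[inwin]))]
  tibble::tibble(onset_ms = big$start_ms, peak_ms = peak,
                 offset_ms = big$end_ms, p = big$p, modulated = TRUE)
}

#' @export
print.modulation_result <- function(x, ...) {
  cat(sprintf("<modulation_result (%s): %d cluster(s), n = %d trials>\n",
              x$contrast, nrow(x$clusters), x$n_trials))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' @describeIn cluster_test_vs_baseline Cluster table of a
#'   `modulation_result`.
#' @param x A `modulation_result`.
#' @param ... Unused.
#' @export
tidy.modulation_result <- function(x, ...) x$clusters

#' @describeIn cluster_test_vs_baseline One-row summary (number of
#'   clusters, minimal p, peak time).
#' @export
glance.modulation_result <- function(x, ...) {
  tibble::tibble(
    contrast = x$contrast,
    n_clusters = nrow(x$clusters),
    min_p = if (nrow(x$clusters)) min(x$clusters$p) else NA_real_,
    peak_ms = x$peak_time,
    n_trials = x$n_trials,
    n_perm = x$n_perm
  )
}
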