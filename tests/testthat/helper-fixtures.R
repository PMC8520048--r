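# Shared fixtures and independent oracles, all built in code.

# Homogeneous Poisson train at a constant rate (spikes/s).
const_train <- function(rate, dur_s, seed, session = "task") {
  sample_poisson_train(rep(rate, dur_s * 1000), seed = seed,
                       session = session)
}

# A small event table on a regular grid.
toy_events <- function(n = 6, categories = rep("face", n), iti = 2.2,
                       first = 1.2) {
  event_table(first + iti * (seq_len(n) - 1), categories)
}

# All permutations of a vector (tiny n only).
all_perms <- function(v) {
  if (length(v) <= 1L) return(matrix(v, nrow = 1L))
  do.call(rbind, lapply(seq_along(v), function(i) {
    cbind(v[i], all_perms(v[-i]), deparse.level = 0)
  }))
}

# Independent oracle for the ranking statistic: exhaustive enumeration of
# every descending ranking consistent with the counts (i.e. all orders
# within tie groups), averaging the spontaneous fraction in the top K.
brute_top_fraction <- function(evoked, spontaneous, threshold) {
  counts <- c(evoked, spontaneous)
  spont <- c(rep(FALSE, length(evoked)), rep(TRUE, length(spontaneous)))
  N <- length(counts)
  K <- round(threshold * N)
  vals <- sort(unique(counts), decreasing = TRUE)
  group_perms <- lapply(vals, function(v) all_perms(which(counts == v)))
  grid <- expand.grid(lapply(group_perms, function(m) seq_len(nrow(m))))
  fracs <- apply(grid, 1, function(sel) {
    ord <- unlist(lapply(seq_along(group_perms), function(g) {
      group_perms[[g]][sel[[g]], ]
    }))
    100 * sum(spont[ord[seq_len(K)]]) / K
  })
  mean(fracs)
}

# Epochs drawn directly from a constant-intensity process, for tests that
# need many cheap null epoch sets.
const_epochs <- function(n_trials, rate, seed, baseline_ms = 500,
                         trial_ms = 1250) {
  withr::with_seed(seed, {
    nb <- baseline_ms + trial_ms
    structure(list(
      counts = matrix(stats::rpois(n_trials * nb, rate / 1000), n_trials,
                      byrow = TRUE),
      rel_time_ms = seq(-baseline_ms, trial_ms - 1),
      events = tibble::tibble(trial = seq_len(n_trials),
                              onset_s = seq_len(n_trials) * 2.2,
                              category = "face"),
      baseline_ms = baseline_ms, trial_ms = trial_ms, resolution_ms = 1
    ), class = "epoch_set")
  })
}
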