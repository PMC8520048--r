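# Helper: epoch set with a deterministic rate elevation/dip injected over a
# known window, on top of constant-intensity noise.
injected_epochs <- function(n_trials, base, delta, from_ms, to_ms, seed) {
  ep <- const_epochs(n_trials, base, seed)
  cols <- which(ep$rel_time_ms >= from_ms & ep$rel_time_ms < to_ms)
  withr::with_seed(seed + 1, {
    extra <- matrix(stats::rpois(n_trials * length(cols), abs(delta) / 1000),
                    n_trials)
  })
  ep$counts[, cols] <- ep$counts[, cols] + sign(delta) * extra
  ep
}

test_that("a strong injected elevation is found as one positive cluster", {
  ep <- injected_epochs(40, base = 15, delta = 35, from_ms = 150,
                        to_ms = 650, seed = 61)
  res <- cluster_test_vs_baseline(ep, n_perm = 500, seed = 1)
  per <- modulation_period(res)
  expect_true(per$modulated)
  expect_lt(per$p, 0.01)
  big <- res$clusters[which.max(abs(res$clusters$mass)), ]
  expect_gt(big$mass, 0)
  # boundaries near the injected window (smoothing widens them outward)
  expect_lt(abs(per$onset_ms - 150), 80)
  expect_lt(abs(per$offset_ms - 650), 80)
})

test_that("flipping the effect sign flips the cluster mass", {
  up <- injected_epochs(40, 30, 25, 200, 600, seed = 67)
  dn <- injected_epochs(40, 30, -25, 200, 600, seed = 67)
  r_up <- cluster_test_vs_baseline(up, n_perm = 300, seed = 2)
  r_dn <- cluster_test_vs_baseline(dn, n_perm = 300, seed = 2)
  m_up <- r_up$clusters[which.max(abs(r_up$clusters$mass)), ]
  m_dn <- r_dn$clusters[which.max(abs(r_dn$clusters$mass)), ]
  expect_gt(m_up$mass, 0)
  expect_lt(m_dn$mass, 0)
})

test_that("no-modulation input yields the explicit empty result", {
  ep <- const_epochs(30, 20, seed = 71)
  res <- cluster_test_vs_baseline(ep, n_perm = 300, seed = 3)
  per <- modulation_period(res)
  if (!per$modulated) {
    expect_true(is.na(per$onset_ms) && is.na(per$peak_ms))
  }
  # all-zero epochs: zero-variance bins give t = 0, no clusters, no error
  ep0 <- const_epochs(10, 0, seed = 73)
  res0 <- cluster_test_vs_baseline(ep0, n_perm = 100, seed = 4)
  expect_equal(nrow(res0$clusters), 0)
  expect_false(modulation_period(res0)$modulated)
})

test_that("with two clusters the larger mass is reported", {
  ep <- const_epochs(40, 15, seed = 79)
  add <- function(ep, from, to, delta, seed) {
    cols <- which(ep$rel_time_ms >= from & ep$rel_time_ms < to)
    withr::with_seed(seed, {
      ep$counts[, cols] <- ep$counts[, cols] +
        matrix(stats::rpois(nrow(ep$counts) * length(cols), delta / 1000),
               nrow(ep$counts))
    })
    ep
  }
  ep <- add(ep, 100, 250, 30, seed = 80)   # small cluster
  ep <- add(ep, 600, 1100, 30, seed = 81)  # large cluster
  res <- cluster_test_vs_baseline(ep, n_perm = 500, seed = 5)
  per <- modulation_period(res)
  expect_true(per$modulated)
  expect_gt(per$onset_ms, 400) # the larger (later, longer) cluster wins
  expect_gt(sum(res$clusters$p < 0.05), 1) # both clusters are significant
})

test_that("between-condition test is antisymmetric under label swap", {
  a <- injected_epochs(25, 15, 30, 200, 700, seed = 83)
  b <- const_epochs(25, 15, seed = 89)
  r_ab <- cluster_test_between(a, b, n_perm = 300, seed = 6)
  r_ba <- cluster_test_between(b, a, n_perm = 300, seed = 6)
  expect_equal(r_ab$t$t, -r_ba$t$t, tolerance = 1e-12)
  expect_equal(sort(abs(r_ab$clusters$mass)), sort(abs(r_ba$clusters$mass)),
               tolerance = 1e-9)
  big <- r_ab$clusters[which.max(abs(r_ab$clusters$mass)), ]
  expect_gt(big$mass, 0)
  expect_lt(big$p, 0.05)
})

test_that("cluster tests are deterministic given data and seed", {
  ep <- injected_epochs(20, 20, 25, 300, 800, seed = 97)
  r1 <- cluster_test_vs_baseline(ep, n_perm = 200, seed = 7)
  r2 <- cluster_test_vs_baseline(ep, n_perm = 200, seed = 7)
  expect_identical(r1$clusters, r2$clusters)
  r3 <- cluster_test_vs_baseline(ep, n_perm = 200, seed = 8)
  expect_false(identical(r1$clusters$p, r3$clusters$p))
})

test_that("tidy and glance summarize a modulation result", {
  ep <- injected_epochs(25, 18, 30, 150, 700, seed = 101)
  res <- cluster_test_vs_baseline(ep, n_perm = 200, seed = 9)
  td <- tidy(res)
  expect_true(all(c("start_ms", "end_ms", "mass", "p") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$n_trials, 25)
  expect_equal(gl$n_perm, 200)
  expect_true(gl$peak_ms >= 0 && gl$peak_ms < 1250)
})
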