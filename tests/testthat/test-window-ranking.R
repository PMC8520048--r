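test_that("window counts equal brute-force sums over the stated interval", {
  tr <- spike_train(c(0.05, 0.12, 0.30, 0.31, 0.90), duration_s = 2)
  on <- c(0, 0.1, 0.3)
  got <- window_counts(tr, on, length_ms = 200)
  brute <- vapply(on, function(o) {
    sum(tr$time_s >= o & tr$time_s < o + 0.2)
  }, numeric(1))
  expect_equal(got, as.integer(brute))
  expect_error(window_counts(tr, 1.9, 200), "overrun")
  expect_error(window_counts(tr, 0, 0.5), "length_ms")

  ep <- const_epochs(5, 40, seed = 141)
  cnt <- window_counts(ep, onsets = 176, length_ms = 100)
  cols <- which(ep$rel_time_ms >= 176 & ep$rel_time_ms < 276)
  expect_equal(cnt, as.integer(rowSums(ep$counts[, cols])))
})

test_that("hand-worked ranking examples", {
  # complete separation: no spontaneous window in the top half
  expect_equal(top_fraction_spontaneous(c(5, 4, 3), c(2, 1, 0), 0.5), 0)
  # full symmetry under proportional ties
  expect_equal(top_fraction_spontaneous(c(1, 1), c(1, 1), 0.5), 50)
  # evoked [3,1], spontaneous [2,2], K = 2: top-2 = {3} plus one of the two
  # tied 2s (both spontaneous) -> 50%
  expect_equal(top_fraction_spontaneous(c(3, 1), c(2, 2), 0.5), 50)
  # K = 0 is rejected
  expect_error(top_fraction_spontaneous(c(1, 2), c(3, 4), 0.1), "K = 0")
  expect_error(top_fraction_spontaneous(1:3, 1:2, 0.5))
})

test_that("proportional ranking equals exhaustive enumeration (<= 8 windows)", {
  withr::with_seed(151, {
    for (n in c(2, 3, 4)) {
      for (rep in 1:8) {
        ev <- stats::rpois(n, 1.2)
        sp <- stats::rpois(n, 1.2)
        for (th in c(0.5, 0.25)) {
          K <- round(th * 2 * n)
          if (K < 1) next
          expect_equal(top_fraction_spontaneous(ev, sp, th),
                       brute_top_fraction(ev, sp, th),
                       tolerance = 1e-12,
                       info = sprintf("n=%d rep=%d th=%g", n, rep, th))
        }
      }
    }
  })
})

test_that("without ties the top-half statistic is a rank computation", {
  withr::with_seed(157, {
    for (rep in 1:10) {
      v <- sample(1000, 12) # distinct values, no ties
      ev <- v[1:6]; sp <- v[7:12]
      got <- top_fraction_spontaneous(ev, sp, 0.5)
      rk <- rank(-c(ev, sp))
      expect_equal(got, 100 * sum(rk[7:12] <= 6) / 6)
    }
  })
})

test_that("spontaneous count in the top-K is non-decreasing in K", {
  withr::with_seed(163, {
    ev <- stats::rpois(70, 3)
    sp <- stats::rpois(70, 3)
    pct <- vapply(c(0.05, 0.2, 0.35, 0.5), function(th) {
      top_fraction_spontaneous(ev, sp, th)
    }, numeric(1))
    counts_in_top <- pct / 100 * round(c(0.05, 0.2, 0.35, 0.5) * 140)
    expect_true(all(diff(counts_in_top) >= -1e-9))
  })
})

test_that("exchangeable counts average exactly 50% under proportional ties", {
  withr::with_seed(167, {
    vals <- replicate(1000, {
      ev <- stats::rpois(10, 0.8)
      sp <- stats::rpois(10, 0.8)
      top_fraction_spontaneous(ev, sp, 0.5)
    })
    expect_lt(abs(mean(vals) - 50), 3)
  })
})

test_that("random tie policy agrees with proportional in expectation", {
  ev <- c(4, 2, 2, 0); sp <- c(3, 2, 2, 1)
  prop <- top_fraction_spontaneous(ev, sp, 0.5)
  withr::with_seed(173, {
    rnd <- mean(replicate(4000, {
      top_fraction_spontaneous(ev, sp, 0.5, tie_policy = "random")
    }))
  })
  expect_lt(abs(rnd - prop), 1.5)
})

test_that("window curves are deterministic and stable to averaging order", {
  study <- generate_study("ctrl", seed = 179)
  ev <- split_parts(study$events)
  ep <- cut_epochs(study$task, ev, "face", part = "part1")
  wc1 <- window_curve(ep, study$resting, peak_ms = 176, lengths_ms = c(10, 50),
                      n_boot = 50, seed = 10)
  wc2 <- window_curve(ep, study$resting, peak_ms = 176, lengths_ms = c(10, 50),
                      n_boot = 50, seed = 10)
  expect_identical(wc1$pct_spontaneous, wc2$pct_spontaneous)
  expect_error(window_curve(ep, const_train(5, 0.1, 1), peak_ms = 176,
                            lengths_ms = 250, n_boot = 2, seed = 1),
               "shorter")
})

test_that("prestimulus comparison uses one window per trial, no bootstrap", {
  study <- generate_study("mu1", seed = 181)
  ev <- split_parts(study$events)
  ep <- cut_epochs(study$task, ev, "face", part = "part1")
  wc <- window_curve(ep, NULL, peak_ms = 176, lengths_ms = c(50, 200),
                     comparison = "prestimulus", n_boot = 999)
  expect_equal(attr(wc, "n_boot"), 1L)
  expect_equal(attr(wc, "n_windows"), 70L)
  # evoked firing dominates the immediate prestimulus interval at 200 ms
  long35 <- wc$pct_spontaneous[wc$length_ms == 200 & wc$threshold == 0.35]
  expect_lt(long35, 10)
})
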