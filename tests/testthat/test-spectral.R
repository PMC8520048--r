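test_that("segment selection follows the stated placement rules", {
  ev <- split_parts(toy_events(10), part1_dur = 350)
  rest <- const_train(10, 30, seed = 111, session = "resting")
  segs <- select_segments(ev, rest, peak_ms = 176, seed = 5)
  faces <- segs[segs$condition == "faces", ]
  pre <- segs[segs$condition == "prestimulus", ]
  rst <- segs[segs$condition == "resting", ]
  # faces segment for peak 176 covers [onset + 0.176, onset + 0.676)
  expect_equal(faces$start_s, ev$onset_s + 0.176)
  # prestimulus segment is the entire 500 ms baseline
  expect_equal(pre$start_s, ev$onset_s - 0.5)
  expect_equal(nrow(rst), nrow(faces))
  expect_true(all(rst$start_s >= 0 & rst$start_s + 0.5 <= 30))
  # reproducible under a fixed seed
  segs2 <- select_segments(ev, rest, peak_ms = 176, seed = 5)
  expect_identical(segs, segs2)
})

test_that("an empty segment has zero power at all frequencies", {
  tr <- spike_train(numeric(0), duration_s = 2)
  ps <- psd_segments(tr, c(0, 0.5, 1))
  expect_true(all(ps$power == 0))
  expect_equal(ps$freq_hz, seq(2, 500, by = 2))
})

test_that("power satisfies Parseval and segments outside the record drop", {
  tr <- const_train(40, 10, seed = 113)
  expect_warning(ps <- psd_segments(tr, c(0.5, 9.9)), "outside")
  expect_equal(nrow(ps$power), 1)
  x <- bin_spikes(tr)[501:1000]
  x <- x - mean(x)
  # Parseval: sum |X_j|^2 = N sum(x^2); in power units (|X|^2 / (N dt))
  # the positive-frequency half doubled plus the Nyquist bin gives
  # sum(x^2) / dt
  expect_equal(2 * sum(ps$power[1, 1:249]) + ps$power[1, 250],
               sum(x^2) * 1000, tolerance = 1e-9)
})

test_that("homogeneous Poisson spectra are flat at the firing rate", {
  lam <- 20
  tr <- const_train(lam, 300, seed = 127)
  ps <- psd_segments(tr, seq(0, 299.5, by = 0.5))
  # point-process theory: flat spectrum at lambda for f > 0
  expect_equal(mean(ps$power), lam, tolerance = 0.03)
  band_lo <- colMeans(ps$power)[ps$freq_hz <= 100]
  band_hi <- colMeans(ps$power)[ps$freq_hz > 400]
  expect_equal(mean(band_lo), mean(band_hi), tolerance = 0.05)
})

test_that("condition spectra separate evoked from spontaneous for mu1", {
  study <- generate_study("mu1", seed = 131)
  ev <- split_parts(study$events)
  segs <- select_segments(ev[ev$part == "part1", ], study$resting,
                          peak_ms = 176, seed = 6)
  psd <- condition_psd(study$task, study$resting, segs)
  m <- tapply(psd$mean_power, psd$condition, mean)
  # evoked faces power dominates both spontaneous conditions across f
  expect_gt(m[["faces"]], 1.5 * m[["resting"]])
  expect_gt(m[["faces"]], 1.5 * m[["prestimulus"]])

  ctrl <- generate_study("ctrl", seed = 137)
  ev_c <- split_parts(ctrl$events)
  segs_c <- select_segments(ev_c[ev_c$part == "part1", ], ctrl$resting,
                            peak_ms = 176, seed = 7)
  psd_c <- condition_psd(ctrl$task, ctrl$resting, segs_c)
  m_c <- tapply(psd_c$mean_power, psd_c$condition, mean)
  # control: conditions indistinguishable (within a few percent)
  expect_lt(max(m_c) / min(m_c), 1.15)
})

test_that("smoothed-input spectra are dominated by the kernel response", {
  tr <- const_train(30, 60, seed = 139)
  ps_b <- psd_segments(tr, seq(0, 59, by = 1), input = "binary")
  ps_s <- psd_segments(tr, seq(0, 59, by = 1), input = "smoothed")
  lo <- ps_s$freq_hz <= 10
  hi <- ps_s$freq_hz >= 100
  # the Gaussian kernel passes low frequencies and crushes high ones
  expect_gt(mean(ps_s$power[, lo]) / mean(ps_s$power[, hi]), 100)
  expect_lt(mean(ps_b$power[, lo]) / mean(ps_b$power[, hi]), 2)
})
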