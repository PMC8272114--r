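test_that("the BSgonio threshold equation matches its closed-form anchors", {
  expect_equal(bsgonio_threshold(0.10, 40, 0), -3.8197, tolerance = 1e-4)
  expect_equal(bsgonio_threshold(0, 40, 20), 20)      # extension peak itself
  expect_equal(bsgonio_threshold(0.5, 40, 20), -20)   # flexion peak
  expect_equal(bsgonio_threshold(0.25, 40, 0), -20)   # mid-range
})

test_that("thresholds for x and 1 - x coincide in angle (cosine evenness)", {
  x <- runif(50)
  expect_equal(bsgonio_threshold(x, 37, 5), bsgonio_threshold(1 - x, 37, 5))
})

test_that("BSgonio matches baseline targets within 1% on clean motion with exact ROM", {
  sim <- clean_sim(n_cycles = 10)
  uni <- upsample_linear(sim$series)
  bp <- compute_baseline_phase(uni, segment_cycles(uni))
  targets <- extract_target_events(bp)
  det <- run_bsgonio(uni, bsgonio_params(rom_deg = 40))
  pr <- pair_events(det[!det$warmup, ], targets)
  expect_equal(pr$ledger$n_false_positive, 0L)
  expect_lt(max(abs(pr$paired$delay_pct)), 1)
})

test_that("a preset ROM wider than the true one biases 10% late and 90% early", {
  sim <- clean_sim(n_cycles = 10, rom_deg = 30)
  uni <- upsample_linear(sim$series)
  bp <- compute_baseline_phase(uni, segment_cycles(uni))
  targets <- extract_target_events(bp)
  det <- run_bsgonio(uni, bsgonio_params(rom_deg = 40))
  pr <- pair_events(det[!det$warmup, ], targets)
  d10 <- pr$paired$delay_pct[pr$paired$level_pct == 10]
  d90 <- pr$paired$delay_pct[pr$paired$level_pct == 90]
  # closed form: the 3.82-degree offset on a 30-degree ROM sits at cycle
  # fraction acos(1 - 2 * 3.82 / 30) / (2 * pi) = 0.1162, not 0.10
  shift <- 100 * (acos(1 - 2 * 3.8197 / 30) / (2 * pi) - 0.10)
  expect_equal(mean(d10), shift, tolerance = 0.2)
  expect_equal(mean(d90), -shift, tolerance = 0.2)
})

test_that("a constant signal produces no BSgonio events", {
  uni <- uniform_angle_series(0, 100, rep(12, 500))
  expect_warning(det <- run_bsgonio(uni), "no confirmed cycle")
  expect_equal(nrow(det), 0L)
})

test_that("Hilbert phase maps the analytic argument to percent as specified", {
  # cosine at its peak: argument 0 -> phase 50
  s <- tone_series(period_s = 1, dur_s = 10, amp = 3)
  ph <- hilbert_phase(s)
  expect_equal(ph$phase[1], 50, tolerance = 0.5)
  # sine at t = 0: argument -pi/2 -> phase 25
  s2 <- tone_series(period_s = 1, dur_s = 10, phi0 = -pi / 2)
  ph2 <- hilbert_phase(s2)
  expect_equal(ph2$phase[1], 25, tolerance = 0.5)
})

test_that("Hilbert phase of a pure tone advances linearly away from the edges", {
  period <- 1.3
  s <- tone_series(period_s = period, dur_s = 13)
  ph <- hilbert_phase(s)
  up <- unwrap_pct(ph$phase)
  core <- ph$t > period / 2 & ph$t < max(ph$t) - period / 2
  fit_slope <- 100 / period
  resid <- up[core] - (up[core][1] + fit_slope * (ph$t[core] - ph$t[core][1]))
  expect_lt(max(abs(resid)), 1)
})

test_that("Hilbert phase is invariant to amplitude scaling and offsets", {
  period <- 2
  base <- tone_series(period_s = period, dur_s = 12)
  scaled <- uniform_angle_series(0, 1000, 7.5 * base$theta + 40)
  p1 <- hilbert_phase(base)
  p2 <- hilbert_phase(scaled)
  core <- p1$t > period / 2 & p1$t < max(p1$t) - period / 2
  expect_lt(max(phase_dist(p1$phase[core], p2$phase[core])), 0.5)
})

test_that("constant input has no defined Hilbert phase", {
  expect_error(hilbert_phase(uniform_angle_series(0, 100, rep(1, 100))),
               "constant")
})

test_that("the GCI observer locks to a pure sine within 2 points RMS", {
  period <- 2.62
  fs <- 1000
  t <- seq(0, 12 * period, by = 1 / fs)
  uni <- uniform_angle_series(0, fs, 20 * cos(2 * pi * t / period))
  ph <- run_gci_observer(uni)
  # ground truth: cos peaks at t = 0, so phase = 100 * t / period mod 100
  truth <- (100 * t / period) %% 100
  core <- t > 3 * period
  err <- phase_dist(ph$phase[core], truth[core])
  expect_lt(sqrt(mean(err^2)), 2)
})

test_that("the GCI frequency estimate follows a cadence step within 5 cycles", {
  fs <- 500
  f1 <- 20 / 60; f2 <- 30 / 60     # 20 -> 30 RPM
  t1 <- seq(0, 8 / f1, by = 1 / fs)                 # 8 cycles at 20 RPM
  t2 <- seq(1 / fs, 5 / f2, by = 1 / fs)            # then 5 cycles at 30 RPM
  phase_true <- c(2 * pi * f1 * t1, 2 * pi * f1 * max(t1) + 2 * pi * f2 * t2)
  uni <- uniform_angle_series(0, fs, 20 * cos(phase_true))
  ph <- run_gci_observer(uni, gci_params(omega_init = 2 * pi * f1))
  omega_end <- attr(ph, "omega_final")
  expect_lt(abs(omega_end - 2 * pi * f2) / (2 * pi * f2), 0.05)
})

test_that("a flat signal holds the GCI phase and flags the samples", {
  uni <- uniform_angle_series(0, 100, rep(5, 300))
  ph <- run_gci_observer(uni)
  expect_true(all(attr(ph, "hold")))
  expect_equal(ph$phase, rep(0, 300))
})

test_that("phase events fall at the level fractions of an exact sawtooth", {
  t <- seq(0, 3, by = 1e-3)
  ph <- phase_series(t, (t %% 1) * 100, source = "saw")
  ev <- phase_to_events(ph)
  lap2 <- ev[ev$time_s > 1 & ev$time_s < 2, ]
  expect_equal(lap2$time_s, 1 + c(0.1, 0.4, 0.6, 0.9), tolerance = 1e-6)
  expect_equal(nrow(ev), 12L)
  expect_true(all(ev$warmup[ev$time_s < 1]))
})

test_that("wrap discontinuities are not crossings", {
  t <- seq(0, 2, by = 1e-2)
  p <- (t %% 1) * 100
  ev <- phase_to_events(phase_series(t, p, "saw"), levels = 90)
  # exactly one 90%-crossing per lap, none at the 100 -> 0 wrap
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$time_s %% 1, rep(0.9, 2), tolerance = 1e-6)
})

test_that("a phase jittering across a level fires once per lap", {
  t <- seq(0, 0.9, by = 0.01)
  p <- t * 100
  # wiggle across the 40 level three times inside one lap
  p[t > 0.40 & t < 0.46] <- c(41, 39, 41, 39, 41)
  ev <- phase_to_events(phase_series(t, p, "wiggly"), levels = 40)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$time_s, 0.4, tolerance = 0.01)
})

test_that("all estimators agree with the baseline within 2% on clean motion", {
  sim <- clean_sim(n_cycles = 12)
  res <- evaluate_recording(sim$series, include_warmup = FALSE)
  for (src in c("bsgonio", "hilbert", "gci")) {
    d <- res$paired$delay_pct[res$paired$source == src]
    # drop each estimator's convergence window (first 3 cycles)
    conv <- res$paired$target_time_s[res$paired$source == src] >
      3 * sim$truth$cycle_durations[1]
    expect_lt(max(abs(d[conv])), 2)
  }
})
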