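test_that("noiseless symmetric motion is a sampled raised cosine with sawtooth phase", {
  sim <- clean_sim(n_cycles = 10, mean_cycle_s = 2.0, seed = 5)
  s <- sim$series
  u <- (s$t %% 2.0) / 2.0
  expect_equal(s$theta, 30 - 40 * (1 - cos(2 * pi * u)) / 2, tolerance = 1e-12)
  # sawtooth ground truth: 100 * fractional cycle position
  expect_equal(phase_dist(sim$truth$true_phase, 100 * u),
               rep(0, length(u)), tolerance = 1e-9)
  expect_equal(length(sim$truth$ext_peak_times), 11L)
  expect_equal(sim$truth$cycle_durations, diff(sim$truth$ext_peak_times))
})

test_that("cycle durations recover the specified truncated-normal mean", {
  sim <- generate_motion(motion_spec(n_cycles = 100, seed = 1))
  dur <- sim$truth$cycle_durations
  # truncation at 0.5 * mean removes ~0.07% of mass: mean shift negligible
  se <- 0.64 / sqrt(100)
  expect_lt(abs(mean(dur) - 2.62), 3 * se)
  expect_true(all(dur >= 0.5 * 2.62))
})

test_that("irregular sampling has the requested mean period and jitter", {
  sim <- generate_motion(motion_spec(n_cycles = 100, mean_fs_hz = 63,
                                     fs_jitter_frac = 0.2, seed = 7))
  dt <- diff(sim$series$t)
  expect_lt(abs(mean(dt) - 1 / 63) / (1 / 63), 0.05)
  expect_gt(stats::sd(dt), 0)
  expect_true(all(dt > 0))
})

test_that("generation is bit-reproducible for a fixed spec and seed", {
  a <- generate_motion(motion_spec(n_cycles = 8, noise_sd_deg = 1, seed = 99))
  b <- generate_motion(motion_spec(n_cycles = 8, noise_sd_deg = 1, seed = 99))
  expect_identical(a, b)
})

test_that("generated angle respects the stated bounds", {
  for (noise in c(0, 1.5)) {
    sim <- generate_motion(motion_spec(n_cycles = 30, noise_sd_deg = noise,
                                       seed = 13))
    expect_true(all(sim$series$theta >= 30 - 40 - 5 * noise - 1e-9))
    expect_true(all(sim$series$theta <= 30 + 5 * noise + 1e-9))
  }
})

test_that("asymmetry moves the flexion peak to fraction 0.5 + asymmetry", {
  sim <- generate_motion(motion_spec(n_cycles = 5, sd_cycle_s = 0,
                                     asymmetry = 0.2, fs_jitter_frac = 0,
                                     seed = 2))
  starts <- sim$truth$ext_peak_times[1:5]
  expect_equal(sim$truth$flex_peak_times,
               starts + 0.7 * sim$truth$cycle_durations, tolerance = 1e-12)
  # flexion peak of the signal sits at the warped fraction
  s <- sim$series
  k <- which(s$t >= starts[2] & s$t < starts[2] + sim$truth$cycle_durations[2])
  t_min <- s$t[k][which.min(s$theta[k])]
  expect_lt(abs(t_min - sim$truth$flex_peak_times[2]), 2 / 63)
})

test_that("invalid specs are rejected naming the field", {
  expect_error(motion_spec(n_cycles = 0), "n_cycles")
  expect_error(motion_spec(5, rom_deg = -1), "rom_deg")
  expect_error(motion_spec(5, asymmetry = 0.6), "asymmetry")
  expect_error(motion_spec(5, fs_jitter_frac = 1.2), "fs_jitter_frac")
})

test_that("rom_shift with factor 1 is the identity", {
  sim <- clean_sim(n_cycles = 4)
  out <- inject_perturbation(sim$series, sim$truth, "rom_shift",
                             list(t_start = 3, factor = 1))
  expect_equal(out$series, sim$series)
  expect_identical(out$truth, sim$truth)
})

test_that("rom_shift rescales the excursion from t_start onward", {
  sim <- clean_sim(n_cycles = 4, mean_cycle_s = 2.0)
  out <- inject_perturbation(sim$series, sim$truth, "rom_shift",
                             list(t_start = 4.0, factor = 0.5))
  pre <- sim$series$t < 4.0
  expect_equal(out$series$theta[pre], sim$series$theta[pre])
  post_range <- diff(range(out$series$theta[!pre]))
  expect_equal(post_range, 20, tolerance = 0.1)
})

test_that("a pause shifts subsequent peak times by its duration", {
  sim <- clean_sim(n_cycles = 4, mean_cycle_s = 2.0)
  # mid-cycle of cycle 2
  out <- inject_perturbation(sim$series, sim$truth, "pause",
                             list(t_start = 3.0, duration = 0.5))
  expect_equal(out$truth$ext_peak_times,
               ifelse(sim$truth$ext_peak_times >= 3.0,
                      sim$truth$ext_peak_times + 0.5,
                      sim$truth$ext_peak_times))
  expect_equal(out$truth$cycle_durations, diff(out$truth$ext_peak_times))
  # held samples carry a frozen phase
  held <- out$series$t >= 3.0 & out$series$t <= 3.5
  expect_lt(diff(range(out$truth$true_phase[held])), 1e-9)
})

test_that("a spike near a flexion peak provokes false positives in BSgonio", {
  sim <- clean_sim(n_cycles = 10, mean_cycle_s = 2.62, seed = 21)
  out <- inject_perturbation(sim$series, sim$truth, "spike",
                             list(t_center = sim$truth$flex_peak_times[5],
                                  amp_deg = 15, width_s = 0.05))
  # targets from the unperturbed motion: the spike is a measurement
  # artifact, not real movement, so extra detections are false positives
  uni_clean <- upsample_linear(sim$series)
  base <- compute_baseline_phase(uni_clean, segment_cycles(uni_clean))
  targets <- suppressWarnings(extract_target_events(base))
  det <- run_bsgonio(upsample_linear(out$series))
  pr <- pair_events(det, targets)
  expect_gte(pr$ledger$n_false_positive + pr$ledger$n_excluded, 1L)
})

test_that("perturbations validate their window and kind", {
  sim <- clean_sim(n_cycles = 2)
  expect_error(inject_perturbation(sim$series, sim$truth, "wobble", list()),
               "unknown kind")
  expect_error(inject_perturbation(sim$series, sim$truth, "spike",
                                   list(t_center = 1e6, amp_deg = 1,
                                        width_s = 0.1)),
               "outside span")
})
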