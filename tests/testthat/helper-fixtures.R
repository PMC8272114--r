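# shared fixtures: all generated in code at test time

# clean symmetric pedalling motion: constant cycle duration, no noise,
# uniform sampling — the analytically tractable case
clean_sim <- function(n_cycles = 10, mean_cycle_s = 2.62, rom_deg = 40,
                      seed = 11, ...) {
  generate_motion(motion_spec(n_cycles = n_cycles,
                              mean_cycle_s = mean_cycle_s, sd_cycle_s = 0,
                              rom_deg = rom_deg, noise_sd_deg = 0,
                              asymmetry = 0, fs_jitter_frac = 0,
                              seed = seed, ...))
}

# uniform pure tone: theta = offset + amp * cos(2*pi*t/period + phi0)
tone_series <- function(period_s, dur_s, fs = 1000, amp = 1, offset = 0,
                        phi0 = 0) {
  t <- seq(0, dur_s, by = 1 / fs)
  uniform_angle_series(0, fs, offset + amp * cos(2 * pi * t / period_s + phi0))
}

# circular distance between two phases in percent of a cycle
phase_dist <- function(a, b) {
  d <- abs(a - b) %% 100
  pmin(d, 100 - d)
}

# unwrap a 0-100 cyclic phase into a monotone sequence
unwrap_pct <- function(p) {
  p + 100 * cumsum(c(0, diff(p) < -50))
}

# brute-force percentile: sort and interpolate order statistics at
# rank position (n - 1) * q + 1 — the independent oracle for the LoA
brute_pctile <- function(x, q) {
  xs <- sort(x)
  n <- length(xs)
  pos <- (n - 1) * q + 1
  k <- floor(pos)
  frac <- pos - k
  if (k >= n) xs[n] else xs[k] + frac * (xs[k + 1] - xs[k])
}
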