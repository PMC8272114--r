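#' Parameters of the adaptive-threshold online peak detector (BSgonio)
#'
#' BSgonio detects events by comparing the thigh angle against thresholds
#' anchored to the most recent extension peak. The range of motion is preset
#' (40 degrees by default, a typical across-subject average) rather than
#' measured, unless `adaptive_rom` is enabled.
#'
#' @param rom_deg Anticipated range of motion in degrees (> 0). Default 40.
#' @param levels Detection phases as fractions in (0, 1).
#'   Default `c(0.10, 0.40, 0.60, 0.90)`.
#' @param hysteresis_deg Signal reversal, in degrees, confirming an online
#'   peak (> 0). Default 4 (10% of the default ROM).
#' @param adaptive_rom If `TRUE`, use the last measured peak-to-peak range
#'   instead of `rom_deg` once one is available. Default `FALSE`.
#' @return An object of class `bsgonio_params`.
#' @export
bsgonio_params <- function(rom_deg = 40, levels = c(0.10, 0.40, 0.60, 0.90),
                           hysteresis_deg = 4, adaptive_rom = FALSE) {
  stopifnot(rom_deg > 0, hysteresis_deg > 0,
            all(levels > 0 & levels < 1))
  structure(list(rom_deg = rom_deg, levels = sort(levels),
                 hysteresis_deg = hysteresis_deg,
                 adaptive_rom = isTRUE(adaptive_rom)),
            class = "bsgonio_params")
}

#' BSgonio threshold for a detection phase
#'
#' The angle threshold that corresponds to a desired detection phase `x`
#' under the raised-cosine cycle model:
#' `Th = Lpk_ext - (ROM - (cos(2*pi*x) + 1) * ROM / 2)`,
#' where `Lpk_ext` is the last extension-peak value in degrees. For
#' `x = 0.10` and `ROM = 40` the threshold sits 3.82 degrees below the
#' extension peak. By cosine evenness the thresholds for `x` and `1 - x`
#' coincide in angle and differ only in crossing direction.
#'
#' @param x Detection phase as a fraction in `[0, 1]`.
#' @param rom_deg Range of motion in degrees (> 0).
#' @param lpk_ext_deg Last extension-peak value in degrees.
#' @return Threshold in degrees.
#' @examples
#' bsgonio_threshold(0.10, 40, 0)   # -3.8197
#' bsgonio_threshold(0.50, 40, 20)  # -20: the flexion peak
#' @export
bsgonio_threshold <- function(x, rom_deg, lpk_ext_deg) {
  stopifnot(all(x >= 0 & x <= 1), rom_deg > 0)
  lpk_ext_deg - (rom_deg - (cos(2 * pi * x) + 1) * rom_deg / 2)
}

#' Run the BSgonio online event detector
#'
#' A strictly single-pass scan of the angle signal. A candidate extremum is
#' confirmed as a peak once the signal has reversed away from it by at least
#' `hysteresis_deg`. After each confirmed extension peak the four thresholds
#' are recomputed from [bsgonio_threshold()] with `Lpk_ext` set to that
#' peak's value. Levels below 0.5 (the flexion half) fire on downward
#' threshold crossings, levels at or above 0.5 (the extension half) on upward
#' crossings; crossing times are linearly interpolated and each level fires
#' at most once per extension-to-extension epoch. Events in the first epoch
#' are flagged `warmup`.
#'
#' @param series A [uniform_angle_series()].
#' @param params A [bsgonio_params()].
#' @return Data frame with columns `source` (`"bsgonio"`), `level_pct`,
#'   `time_s`, `warmup`. Empty (with a warning) if no peak is ever confirmed.
#' @export
run_bsgonio <- function(series, params = bsgonio_params()) {
  stopifnot(inherits(series, "uniform_angle_series"),
            inherits(params, "bsgonio_params"))
  th <- series$theta
  t <- series_times(series)
  n <- length(th)
  hyst <- params$hysteresis_deg
  lv <- params$levels
  going_down <- lv < 0.5

  ev_level <- numeric(0); ev_time <- numeric(0); ev_epoch <- integer(0)
  thr <- NULL
  fired <- rep(TRUE, length(lv))
  epoch <- 0L
  last_flex_val <- NA_real_

  cross <- function(j) {
    for (k in seq_along(lv)) {
      if (fired[k]) next
      a <- th[j - 1L]; b <- th[j]; Tk <- thr[k]
      hit <- if (going_down[k]) (a > Tk && b <= Tk) else (a < Tk && b >= Tk)
      if (hit) {
        tc <- t[j - 1L] + (Tk - a) / (b - a) * (t[j] - t[j - 1L])
        ev_level <<- c(ev_level, 100 * lv[k])
        ev_time <<- c(ev_time, tc)
        ev_epoch <<- c(ev_epoch, epoch)
        fired[k] <<- TRUE
      }
    }
  }

  mode <- 0L
  mx_v <- th[1L]; mx_i <- 1L
  mn_v <- th[1L]; mn_i <- 1L
  for (i in 2:n) {
    if (th[i] > mx_v) { mx_v <- th[i]; mx_i <- i }
    if (th[i] < mn_v) { mn_v <- th[i]; mn_i <- i }
    if (mode != -1L && mx_v - th[i] >= hyst) {
      # extension peak confirmed: new epoch, thresholds from this peak
      epoch <- epoch + 1L
      rom <- if (params$adaptive_rom && !is.na(last_flex_val)) {
        mx_v - last_flex_val
      } else params$rom_deg
      thr <- bsgonio_threshold(lv, rom, mx_v)
      fired <- rep(FALSE, length(lv))
      # the crossing may already lie between the peak and its confirmation
      for (j in max(2L, mx_i + 1L):i) cross(j)
      mode <- -1L
      mn_v <- th[i]; mn_i <- i
    } else {
      if (mode != 1L && th[i] - mn_v >= hyst) {
        last_flex_val <- mn_v
        mode <- 1L
        mx_v <- th[i]; mx_i <- i
      }
      if (!is.null(thr)) cross(i)
    }
  }
  if (epoch == 0L) {
    warning("run_bsgonio: no confirmed cycle in input")
  }
  ord <- order(ev_time)
  data.frame(source = rep("bsgonio", length(ev_time)),
             level_pct = ev_level[ord], time_s = ev_time[ord],
             warmup = ev_epoch[ord] == 1L)
}

#' Instantaneous phase from the Hilbert transform
#'
#' Computes the analytic representation of the mean-removed angle signal via
#' the discrete Hilbert transform (FFT half-spectrum construction) and maps
#' its argument, in `(-pi, pi]`, to a cycle phase in percent:
#' `phase = (arg / pi + 1) * 50`. The whole signal must be known, so this
#' estimator is offline only. Note the convention: a pure cosine evaluated at
#' its maximum has argument 0 and therefore phase 50; use [rotate_phase()]
#' to align with a phase convention that puts 0 at the signal maximum.
#'
#' @param series A [uniform_angle_series()] of at least 4 samples.
#' @return An object of class `phase_series`: data frame with columns `t`,
#'   `phase` (percent in `[0, 100)`) and attribute `source = "hilbert"`.
#' @export
hilbert_phase <- function(series) {
  stopifnot(inherits(series, "uniform_angle_series"))
  x <- series$theta - mean(series$theta)
  n <- length(x)
  if (n < 4L) stop("hilbert_phase: need at least 4 samples", call. = FALSE)
  if (max(abs(x)) < sqrt(.Machine$double.eps)) {
    stop("hilbert_phase: constant input has no defined phase", call. = FALSE)
  }
  # analytic signal: double the positive frequencies, zero the negative ones
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  analytic <- stats::fft(stats::fft(x) * h, inverse = TRUE) / n
  phase <- (Arg(analytic) / pi + 1) * 50
  phase_series(series_times(series), phase %% 100, source = "hilbert")
}

#' Phase series container
#'
#' @param t Sample times in seconds.
#' @param phase Cycle phase in percent, wrapping 100 -> 0.
#' @param source Estimator name.
#' @return An object of class `phase_series`.
#' @export
phase_series <- function(t, phase, source) {
  structure(data.frame(t = as.numeric(t), phase = as.numeric(phase)),
            source = source, class = c("phase_series", "data.frame"))
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("phase_series [%s]: %d samples over %.2f s\n",
              attr(x, "source"), nrow(x), x$t[nrow(x)] - x$t[1L]))
  invisible(x)
}

#' Rotate a cyclic phase by a constant offset
#'
#' @param phase A [phase_series()].
#' @param offset_pct Offset in percent of a cycle; the result is taken
#'   modulo 100.
#' @return A [phase_series()] with the same source.
#' @export
rotate_phase <- function(phase, offset_pct) {
  stopifnot(inherits(phase, "phase_series"))
  phase_series(phase$t, (phase$phase + offset_pct) %% 100,
               source = attr(phase, "source"))
}

#' Parameters of the oscillator-based phase observer (GCI Observer)
#'
#' The observer mimics a central pattern generator: an internal oscillator
#' with phase and frequency state is continuously pulled toward the phase
#' measured from the normalised angle and angular velocity against a sine
#' reference model. The equations here are this package's documented,
#' config-exposed variant of that scheme; all gains are tunable.
#'
#' @param k_phase Phase-correction gain in 1/s. Default 5.
#' @param k_freq Frequency-adaptation gain in 1/s^2. Default 2.
#' @param omega_init Initial angular frequency in rad/s. Default
#'   `2 * pi / 2.62` (the typical passive-cycling cadence of 24.1 RPM).
#' @param amp_tau_s Time constant, in seconds, of the running midpoint and
#'   amplitude estimates. Default 3.
#' @param vel_lp_hz Cut-off, in Hz, of the causal first-order low-pass on the
#'   finite-difference velocity. Default 5.
#' @param amp_floor_deg Amplitude below which the signal is treated as flat
#'   and the phase is held. Default 0.5.
#' @return An object of class `gci_params`.
#' @export
gci_params <- function(k_phase = 5, k_freq = 2, omega_init = 2 * pi / 2.62,
                       amp_tau_s = 3, vel_lp_hz = 5, amp_floor_deg = 0.5) {
  stopifnot(k_phase > 0, k_freq > 0, omega_init > 0, amp_tau_s > 0,
            vel_lp_hz > 0, amp_floor_deg > 0)
  structure(list(k_phase = k_phase, k_freq = k_freq, omega_init = omega_init,
                 amp_tau_s = amp_tau_s, vel_lp_hz = vel_lp_hz,
                 amp_floor_deg = amp_floor_deg),
            class = "gci_params")
}

wrap_pi <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  ifelse(w == -pi, pi, w)
}

#' Run the GCI Observer phase estimator
#'
#' Causal per-sample recursion. (1) Running midpoint and amplitude estimates
#' (exponential averaging with time constant `amp_tau_s`, warm-started as a
#' running mean) normalise the angle. (2) The finite-difference velocity is
#' low-passed at `vel_lp_hz` and normalised by the current frequency
#' estimate. (3) The measured phase for the sine reference model
#' `theta_ref = cos(phi)` is `phi_m = atan2(-vel_n, theta_n)`. (4) The
#' observer integrates `phi_hat <- phi_hat + (omega_hat + k_phase * e) * dt`
#' and adapts `omega_hat <- omega_hat + k_freq * e * dt` with the wrapped
#' error `e = wrap(phi_m - phi_hat)`. Output is `wrap(phi_hat)` scaled to
#' percent. When the running amplitude falls below `amp_floor_deg` the phase
#' is held and the sample flagged.
#'
#' @param series A [uniform_angle_series()] with `fs` at most 1000 Hz (the
#'   highest rate the observer's input model accepts).
#' @param params A [gci_params()].
#' @return A [phase_series()] with source `"gci"` and a logical attribute
#'   `hold` marking flat-signal samples.
#' @export
run_gci_observer <- function(series, params = gci_params()) {
  stopifnot(inherits(series, "uniform_angle_series"),
            inherits(params, "gci_params"))
  if (series$fs > 1000) {
    stop("run_gci_observer: input model accepts at most 1000 Hz", call. = FALSE)
  }
  th <- series$theta
  n <- length(th)
  dt <- 1 / series$fs
  a_ema <- 1 - exp(-dt / params$amp_tau_s)
  b_lp <- 1 - exp(-2 * pi * params$vel_lp_hz * dt)

  m <- th[1L]
  a <- 0
  v <- 0
  omega <- params$omega_init
  phi <- 0
  phase <- numeric(n)
  hold <- logical(n)
  phase[1L] <- 0
  hold[1L] <- TRUE
  for (i in 2:n) {
    # warm start: running mean for the first samples, EMA afterwards
    al <- max(a_ema, 1 / i)
    m <- m + al * (th[i] - m)
    dev <- th[i] - m
    a <- a + al * ((pi / 2) * abs(dev) - a)
    v <- v + b_lp * ((th[i] - th[i - 1L]) / dt - v)
    if (a < params$amp_floor_deg) {
      hold[i] <- TRUE
      phase[i] <- phase[i - 1L]
      next
    }
    theta_n <- dev / a
    vel_n <- v / (a * omega)
    phi_m <- atan2(-vel_n, theta_n)
    e <- wrap_pi(phi_m - phi)
    phi <- phi + (omega + params$k_phase * e) * dt
    omega <- omega + params$k_freq * e * dt
    phase[i] <- (phi %% (2 * pi)) / (2 * pi) * 100
  }
  out <- phase_series(series_times(series), phase, source = "gci")
  attr(out, "hold") <- hold
  attr(out, "omega_final") <- omega
  out
}

#' Detect events from a phase series
#'
#' Events are upward crossings of each threshold level, linearly
#' interpolated between bracketing samples. Wrap discontinuities (large
#' negative jumps, 100 -> 0) delimit laps and are never themselves
#' crossings; within one lap each level fires at most once, at its first
#' crossing. Events in the first (possibly partial) lap are flagged
#' `warmup`.
#'
#' @param phase A [phase_series()].
#' @param levels Threshold levels in percent. Default `c(10, 40, 60, 90)`.
#' @param source Source label for the output; defaults to the series source.
#' @return Data frame with columns `source`, `level_pct`, `time_s`, `warmup`.
#' @export
phase_to_events <- function(phase, levels = c(10, 40, 60, 90), source = NULL) {
  stopifnot(inherits(phase, "phase_series"))
  if (is.null(source)) source <- attr(phase, "source")
  p <- phase$phase
  t <- phase$t
  if (length(p) < 2L) {
    return(data.frame(source = character(), level_pct = numeric(),
                      time_s = numeric(), warmup = logical()))
  }
  d <- diff(p)
  lap <- cumsum(c(0L, d < -50))
  out <- list()
  for (L in sort(levels)) {
    j <- which(d > 0 & p[-length(p)] < L & p[-1L] >= L)
    if (length(j) == 0L) next
    keep <- j[!duplicated(lap[j])]  # first crossing per lap
    tc <- t[keep] + (L - p[keep]) / (p[keep + 1L] - p[keep]) *
      (t[keep + 1L] - t[keep])
    out[[length(out) + 1L]] <- data.frame(source = source, level_pct = L,
                                          time_s = tc,
                                          warmup = lap[keep] == 0L)
  }
  if (length(out) == 0L) {
    return(data.frame(source = character(), level_pct = numeric(),
                      time_s = numeric(), warmup = logical()))
  }
  ev <- do.call(rbind, out)
  ev[order(ev$time_s), , drop = FALSE]
}
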