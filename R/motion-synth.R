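#' Specification of a synthetic pedalling motion
#'
#' Describes the recording conditions a synthetic thigh-angle series should
#' emulate: quasi-sinusoidal inclination with per-cycle durations drawn from a
#' truncated normal, a fixed range of motion, optional additive noise and
#' flexion/extension asymmetry, and irregular sampling around a mean rate.
#' Defaults mirror passive FES-cycling recordings in adults with spinal cord
#' injury: mean cycle duration 2.62 s (SD 0.64 s, i.e. cadence 24.1 +/- 4.9
#' RPM), range of motion 40 degrees, sampling around 63 Hz.
#'
#' @param n_cycles Number of complete pedalling cycles (>= 1).
#' @param mean_cycle_s Mean cycle duration in seconds (> 0). Default 2.62.
#' @param sd_cycle_s SD of cycle duration in seconds. Default 0.64. Durations
#'   are truncated below at `0.5 * mean_cycle_s` so no near-zero cycle occurs.
#' @param rom_deg Range of motion in degrees (> 0). Default 40.
#' @param ext_peak_deg Angle at full leg extension in degrees. Default 30.
#' @param noise_sd_deg SD of additive Gaussian measurement noise in degrees.
#'   Default 0.
#' @param asymmetry In `[-0.4, 0.4]`; skews the flexion half so the flexion
#'   peak falls at cycle fraction `0.5 + asymmetry`. Default 0 (symmetric).
#' @param mean_fs_hz Mean sampling frequency in Hz. Default 63.
#' @param fs_jitter_frac Uniform jitter of each sampling period as a fraction
#'   of the mean period (>= 0, < 1). Default 0.2.
#' @param seed Integer seed; the generator is bit-reproducible for a fixed
#'   spec and seed.
#' @return An object of class `motion_spec`.
#' @export
motion_spec <- function(n_cycles,
                        mean_cycle_s = 2.62, sd_cycle_s = 0.64,
                        rom_deg = 40, ext_peak_deg = 30,
                        noise_sd_deg = 0, asymmetry = 0,
                        mean_fs_hz = 63, fs_jitter_frac = 0.2,
                        seed = 1L) {
  chk <- function(ok, field, what) {
    if (!isTRUE(ok)) {
      stop(sprintf("motion_spec: '%s' %s", field, what), call. = FALSE)
    }
  }
  chk(is.numeric(n_cycles) && n_cycles >= 1, "n_cycles", "must be >= 1")
  chk(is.numeric(mean_cycle_s) && mean_cycle_s > 0, "mean_cycle_s", "must be > 0")
  chk(is.numeric(sd_cycle_s) && sd_cycle_s >= 0, "sd_cycle_s", "must be >= 0")
  chk(is.numeric(rom_deg) && rom_deg > 0, "rom_deg", "must be > 0")
  chk(is.numeric(noise_sd_deg) && noise_sd_deg >= 0, "noise_sd_deg", "must be >= 0")
  chk(is.numeric(asymmetry) && abs(asymmetry) <= 0.4, "asymmetry",
      "must be in [-0.4, 0.4]")
  chk(is.numeric(mean_fs_hz) && mean_fs_hz > 0, "mean_fs_hz", "must be > 0")
  chk(is.numeric(fs_jitter_frac) && fs_jitter_frac >= 0 && fs_jitter_frac < 1,
      "fs_jitter_frac", "must be in [0, 1)")
  structure(list(n_cycles = as.integer(n_cycles), mean_cycle_s = mean_cycle_s,
                 sd_cycle_s = sd_cycle_s, rom_deg = rom_deg,
                 ext_peak_deg = ext_peak_deg, noise_sd_deg = noise_sd_deg,
                 asymmetry = asymmetry, mean_fs_hz = mean_fs_hz,
                 fs_jitter_frac = fs_jitter_frac, seed = as.integer(seed)),
            class = "motion_spec")
}

#' @export
print.motion_spec <- function(x, ...) {
  cat(sprintf(paste0("motion_spec: %d cycles, duration %.2f +/- %.2f s, ",
                     "ROM %g deg, noise %g deg, fs %g Hz (jitter %g), seed %d\n"),
              x$n_cycles, x$mean_cycle_s, x$sd_cycle_s, x$rom_deg,
              x$noise_sd_deg, x$mean_fs_hz, x$fs_jitter_frac, x$seed))
  invisible(x)
}

# two-segment linear time warp: cycle fraction u -> phase fraction g(u),
# placing the flexion peak (g = 0.5) at u = 0.5 + asymmetry
warp_fraction <- function(u, asymmetry) {
  if (asymmetry == 0) return(u)
  p <- 0.5 + asymmetry
  ifelse(u <= p, 0.5 * u / p, 0.5 + 0.5 * (u - p) / (1 - p))
}

# truncated-normal draws by rejection (exact, seed-deterministic)
rtnorm_lower <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0L) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic pedalling recording with ground truth
#'
#' Produces an irregularly sampled thigh-inclination series together with the
#' exact phase and peak times that generated it. Within each cycle the
#' noiseless angle is a raised cosine of the (optionally time-warped) cycle
#' fraction,
#' `theta(u) = ext_peak_deg - rom_deg * (1 - cos(2*pi*g(u))) / 2`,
#' so the extension peak (signal maximum) marks phase 0/100 and the flexion
#' peak (minimum) phase 50. Cycle durations are truncated-normal; sample times
#' have a uniformly jittered period. Ground-truth phase is `100 * g(u)`.
#'
#' @param spec A [motion_spec()].
#' @return A list with elements:
#'   \describe{
#'     \item{series}{an [angle_series()] of the noisy sampled angle;}
#'     \item{truth}{a list with `true_phase` (percent, aligned to the sample
#'       times), `ext_peak_times`, `flex_peak_times`, `cycle_durations`
#'       (all seconds).}
#'   }
#' @examples
#' sim <- generate_motion(motion_spec(n_cycles = 5, seed = 42))
#' sim$series
#' length(sim$truth$ext_peak_times)  # n_cycles + 1
#' @export
generate_motion <- function(spec) {
  stopifnot(inherits(spec, "motion_spec"))
  with_local_seed(spec$seed, {
    dur <- rtnorm_lower(spec$n_cycles, spec$mean_cycle_s, spec$sd_cycle_s,
                        0.5 * spec$mean_cycle_s)
    ext_peaks <- c(0, cumsum(dur))
    total <- ext_peaks[length(ext_peaks)]

    period <- 1 / spec$mean_fs_hz
    n_max <- ceiling(total / (period * (1 - spec$fs_jitter_frac))) + 2L
    jit <- if (spec$fs_jitter_frac > 0) {
      stats::runif(n_max, -spec$fs_jitter_frac, spec$fs_jitter_frac)
    } else rep(0, n_max)
    t <- cumsum(period * (1 + jit))
    t <- c(0, t[t < total], total)

    cyc <- findInterval(t, ext_peaks, rightmost.closed = TRUE)
    cyc <- pmin(pmax(cyc, 1L), spec$n_cycles)
    u <- (t - ext_peaks[cyc]) / dur[cyc]
    g <- warp_fraction(u, spec$asymmetry)
    theta0 <- spec$ext_peak_deg - spec$rom_deg * (1 - cos(2 * pi * g)) / 2
    noise <- if (spec$noise_sd_deg > 0) {
      stats::rnorm(length(t), 0, spec$noise_sd_deg)
    } else 0
    series <- angle_series(t, theta0 + noise)

    truth <- list(true_phase = 100 * g,
                  ext_peak_times = ext_peaks,
                  flex_peak_times = ext_peaks[seq_len(spec$n_cycles)] +
                    (0.5 + spec$asymmetry) * dur,
                  cycle_durations = dur)
    list(series = series, truth = truth)
  })
}

#' Inject a perturbation into a synthetic recording
#'
#' Reproduces, as parameterised primitives, the kinds of rapid shape
#' variations in the thigh-angle signal that provoke false detections in
#' practice: a range-of-motion change (`rom_shift`), a momentary hold of the
#' motion (`pause`), and a short transient (`spike`). Ground truth is updated
#' consistently (frozen phase during a pause, shifted peak times after it).
#'
#' @param series An [angle_series()].
#' @param truth The matching ground-truth list from [generate_motion()].
#' @param kind One of `"rom_shift"`, `"pause"`, `"spike"`.
#' @param params A named list:
#'   \describe{
#'     \item{rom_shift}{`t_start` (s), `factor` (> 0): from `t_start` onward
#'       the excursion below the extension-peak level is rescaled by `factor`;
#'       `factor = 1` is the identity.}
#'     \item{pause}{`t_start` (s), `duration` (s): the motion freezes for
#'       `duration`; all samples and peak times after `t_start` shift by
#'       `+duration` and held samples are inserted.}
#'     \item{spike}{`t_center` (s), `amp_deg`, `width_s`: adds a raised-cosine
#'       bump of half-width `width_s/2`.}
#'   }
#' @return A list `(series, truth)` like [generate_motion()].
#' @export
inject_perturbation <- function(series, truth, kind, params = list()) {
  stopifnot(inherits(series, "angle_series"))
  span <- range(series$t)
  inside <- function(x) x >= span[1L] && x <= span[2L]
  get_par <- function(name) {
    if (is.null(params[[name]])) {
      stop(sprintf("inject_perturbation: missing parameter '%s'", name),
           call. = FALSE)
    }
    params[[name]]
  }
  if (identical(kind, "rom_shift")) {
    t_start <- get_par("t_start"); factor <- get_par("factor")
    if (!inside(t_start)) {
      stop("inject_perturbation: window outside span", call. = FALSE)
    }
    anchor <- max(series$theta)
    sel <- series$t >= t_start
    theta <- series$theta
    theta[sel] <- anchor - factor * (anchor - theta[sel])
    list(series = angle_series(series$t, theta), truth = truth)
  } else if (identical(kind, "pause")) {
    t_start <- get_par("t_start"); duration <- get_par("duration")
    if (!inside(t_start)) {
      stop("inject_perturbation: window outside span", call. = FALSE)
    }
    hold_theta <- stats::approx(series$t, series$theta, xout = t_start)$y
    hold_phase <- stats::approx(series$t, truth$true_phase, xout = t_start)$y
    pre <- series$t < t_start
    dt_mean <- mean(diff(series$t))
    t_ins <- seq(t_start, t_start + duration, by = dt_mean)
    t_new <- c(series$t[pre], t_ins, series$t[!pre] + duration)
    th_new <- c(series$theta[pre], rep(hold_theta, length(t_ins)),
                series$theta[!pre])
    ph_new <- c(truth$true_phase[pre], rep(hold_phase, length(t_ins)),
                truth$true_phase[!pre])
    shift <- function(x) ifelse(x >= t_start, x + duration, x)
    truth2 <- truth
    truth2$true_phase <- ph_new
    truth2$ext_peak_times <- shift(truth$ext_peak_times)
    truth2$flex_peak_times <- shift(truth$flex_peak_times)
    truth2$cycle_durations <- diff(truth2$ext_peak_times)
    list(series = angle_series(t_new, th_new), truth = truth2)
  } else if (identical(kind, "spike")) {
    t_center <- get_par("t_center"); amp <- get_par("amp_deg")
    width <- get_par("width_s")
    if (!inside(t_center)) {
      stop("inject_perturbation: window outside span", call. = FALSE)
    }
    h <- width / 2
    bump <- ifelse(abs(series$t - t_center) <= h,
                   amp * 0.5 * (1 + cos(pi * (series$t - t_center) / h)), 0)
    list(series = angle_series(series$t, series$theta + bump), truth = truth)
  } else {
    stop(sprintf("inject_perturbation: unknown kind '%s'", kind), call. = FALSE)
  }
}
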