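#' Time-stamped thigh-inclination series
#'
#' An `angle_series` holds an irregularly sampled single-channel angle signal:
#' the inclination of the thigh segment relative to the horizontal plane, in
#' degrees, against time in seconds. It is the common input of every estimator
#' in the package.
#'
#' @param t Numeric vector of sample times in seconds, strictly increasing.
#' @param theta Numeric vector of angles in degrees, same length as `t`.
#' @return An object of class `angle_series`: a data frame with columns
#'   `t` and `theta`.
#' @examples
#' s <- angle_series(c(0, 0.016, 0.032), c(30, 29.2, 27.1))
#' s
#' @export
angle_series <- function(t, theta) {
  t <- as.numeric(t)
  theta <- as.numeric(theta)
  if (length(t) != length(theta)) {
    stop("angle_series: 't' and 'theta' must have equal length", call. = FALSE)
  }
  if (length(t) < 2L) {
    stop("angle_series: need at least 2 samples", call. = FALSE)
  }
  bad <- which(!is.finite(t) | !is.finite(theta))
  if (length(bad) > 0L) {
    stop(sprintf("angle_series: non-finite value at row %d", bad[1L]),
         call. = FALSE)
  }
  if (any(diff(t) <= 0)) {
    stop("angle_series: non-monotonic time", call. = FALSE)
  }
  structure(data.frame(t = t, theta = theta), class = c("angle_series", "data.frame"))
}

#' @export
print.angle_series <- function(x, ...) {
  dt <- diff(x$t)
  cat(sprintf("angle_series: %d samples over %.3f s (mean rate %.1f Hz)\n",
              nrow(x), x$t[nrow(x)] - x$t[1L], 1 / mean(dt)))
  cat(sprintf("  theta range: [%.2f, %.2f] deg\n", min(x$theta), max(x$theta)))
  invisible(x)
}

#' Uniformly sampled angle series
#'
#' Holds an angle signal on a uniform time grid `t0 + k/fs`. Produced by
#' [upsample_linear()]; consumed by the cycle segmentation and all estimators.
#'
#' @param t0 Start time in seconds.
#' @param fs Sampling frequency in Hz (> 0).
#' @param theta Numeric vector of angles in degrees.
#' @return An object of class `uniform_angle_series` with fields `t0`, `fs`,
#'   `theta`.
#' @export
uniform_angle_series <- function(t0, fs, theta) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("uniform_angle_series: 'fs' must be a positive scalar", call. = FALSE)
  }
  theta <- as.numeric(theta)
  if (any(!is.finite(theta))) {
    stop("uniform_angle_series: non-finite theta", call. = FALSE)
  }
  structure(list(t0 = as.numeric(t0), fs = as.numeric(fs), theta = theta),
            class = "uniform_angle_series")
}

#' Sample times of a uniform series
#'
#' @param x A `uniform_angle_series`.
#' @return Numeric vector `t0 + (0:(n-1))/fs`.
#' @export
series_times <- function(x) {
  stopifnot(inherits(x, "uniform_angle_series"))
  x$t0 + (seq_along(x$theta) - 1L) / x$fs
}

#' @export
print.uniform_angle_series <- function(x, ...) {
  cat(sprintf("uniform_angle_series: %d samples at %g Hz from t0 = %.3f s\n",
              length(x$theta), x$fs, x$t0))
  invisible(x)
}
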