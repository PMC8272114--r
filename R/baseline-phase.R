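#' Segment a cyclic angle signal into pedalling cycles
#'
#' Delimits cycles by the peaks of the thigh-angle movement, from one peak of
#' leg extension (local maximum of the signal) to the next. Peaks are found by
#' an alternating extremum scan: a running extremum is confirmed as a peak
#' once the signal has reversed away from it by at least
#' `min_prominence_deg`, which enforces ext/flex alternation by construction
#' and also captures the boundary extrema at the start and end of a
#' recording. Confirmed extension peaks closer together than `min_period_s`
#' are merged by keeping the more extreme of the same-kind neighbours.
#'
#' @param series A [uniform_angle_series()] spanning at least 2 cycles.
#' @param min_prominence_deg Minimum reversal, in degrees, confirming a peak.
#'   Default: 25% of the observed signal range.
#' @param min_period_s Minimum separation of extension peaks in seconds.
#'   Default 0.5 (half the shortest plausible cycle at 60 RPM).
#' @return An object of class `cycle_segmentation`: list with integer sample
#'   indices `ext_peak_idx` (local maxima) and `flex_peak_idx` (local minima),
#'   alternating ext, flex, ext, ...
#' @export
segment_cycles <- function(series, min_prominence_deg = NULL,
                           min_period_s = 0.5) {
  stopifnot(inherits(series, "uniform_angle_series"))
  th <- series$theta
  n <- length(th)
  if (is.null(min_prominence_deg)) {
    min_prominence_deg <- 0.25 * diff(range(th))
  }
  if (min_prominence_deg <= 0) {
    stop("segment_cycles: no complete cycle (flat signal)", call. = FALSE)
  }

  idx <- integer(0)
  kind <- integer(0)  # +1 = ext (max), -1 = flex (min)
  mode <- 0L          # +1 ascending (tracking a max), -1 descending
  mx_v <- th[1L]; mx_i <- 1L
  mn_v <- th[1L]; mn_i <- 1L
  for (i in 2:n) {
    if (th[i] > mx_v) { mx_v <- th[i]; mx_i <- i }
    if (th[i] < mn_v) { mn_v <- th[i]; mn_i <- i }
    if (mode != -1L && mx_v - th[i] >= min_prominence_deg) {
      idx <- c(idx, mx_i); kind <- c(kind, 1L)
      mode <- -1L
      mn_v <- th[i]; mn_i <- i
    } else if (mode != 1L && th[i] - mn_v >= min_prominence_deg) {
      idx <- c(idx, mn_i); kind <- c(kind, -1L)
      mode <- 1L
      mx_v <- th[i]; mx_i <- i
    }
  }
  # trailing extremum at the recording boundary
  if (mode == 1L && length(idx) > 0L && mx_v - th[idx[length(idx)]] >= min_prominence_deg) {
    idx <- c(idx, mx_i); kind <- c(kind, 1L)
  } else if (mode == -1L && length(idx) > 0L &&
             th[idx[length(idx)]] - mn_v >= min_prominence_deg) {
    idx <- c(idx, mn_i); kind <- c(kind, -1L)
  }

  # merge extension peaks closer than min_period_s (keep the more extreme
  # same-kind neighbour after dropping the pair between them)
  repeat {
    ext_pos <- which(kind == 1L)
    if (length(ext_pos) < 2L) break
    dt <- diff(idx[ext_pos]) / series$fs
    v <- which(dt < min_period_s)
    if (length(v) == 0L) break
    a <- ext_pos[v[1L]]; b <- ext_pos[v[1L] + 1L]
    drop_ext <- if (th[idx[a]] >= th[idx[b]]) b else a
    between <- which(kind == -1L & seq_along(idx) > a & seq_along(idx) < b)
    keep_flex <- between[which.min(th[idx[between]])]
    drop <- setdiff(c(a:b), c(setdiff(c(a, b), drop_ext), keep_flex))
    idx <- idx[-drop]; kind <- kind[-drop]
  }

  ext <- idx[kind == 1L]
  flx <- idx[kind == -1L]
  if (length(ext) < 2L) {
    stop("segment_cycles: no complete cycle", call. = FALSE)
  }
  # trim leading/trailing flex peaks outside the first/last extension peak
  flx <- flx[flx > ext[1L] & flx < ext[length(ext)]]
  structure(list(ext_peak_idx = ext, flex_peak_idx = flx,
                 fs = series$fs, t0 = series$t0),
            class = "cycle_segmentation")
}

#' @export
print.cycle_segmentation <- function(x, ...) {
  cat(sprintf("cycle_segmentation: %d extension peaks, %d flexion peaks (%d cycles)\n",
              length(x$ext_peak_idx), length(x$flex_peak_idx),
              length(x$ext_peak_idx) - 1L))
  invisible(x)
}

#' Linearised per-cycle baseline phase
#'
#' Computes the a-posteriori phase reference against which event detections
#' are judged. Each cycle is split at its flexion peak into a flexion half
#' (phase 0 to 50%) and an extension half (50 to 100%). Each half is
#' normalised by its own peak-to-peak angle range and linearised through the
#' arc cosine — the signal originates from a circular motion, so the arc
#' cosine of the normalised angle recovers a linear cycle progression. For
#' the flexion half with extension-peak value `A_e` and flexion-peak value
#' `A_f`: `u = 2 * (theta - A_f) / (A_e - A_f) - 1` (clipped to `[-1, 1]`),
#' `phase = 50 * acos(u) / pi`; for the extension half the same normalisation
#' against the closing extension peak gives `phase = 100 - 50 * acos(u) / pi`.
#'
#' Samples before the first extension peak and after the last are marked
#' out-of-cycle (`NA`). A cycle whose half has zero angle range is flagged
#' and excluded.
#'
#' @param series A [uniform_angle_series()].
#' @param seg The matching [segment_cycles()] result.
#' @return An object of class `baseline_phase`: a data frame with columns
#'   `t` (s), `phase` (percent in `[0, 100]`) and `cycle_id` (`NA` outside
#'   complete cycles), with a `cycles` attribute (data frame `cycle_id`,
#'   `t_start`, `t_end`, `duration`, `excluded`).
#' @export
compute_baseline_phase <- function(series, seg) {
  stopifnot(inherits(series, "uniform_angle_series"),
            inherits(seg, "cycle_segmentation"))
  th <- series$theta
  t <- series_times(series)
  n_cyc <- length(seg$ext_peak_idx) - 1L
  phase <- rep(NA_real_, length(th))
  cycle_id <- rep(NA_integer_, length(th))
  info <- data.frame(cycle_id = seq_len(n_cyc), t_start = NA_real_,
                     t_end = NA_real_, duration = NA_real_, excluded = FALSE)

  half_phase <- function(idx, A_top, A_bot, extension) {
    u <- 2 * (th[idx] - A_bot) / (A_top - A_bot) - 1
    u <- pmin(1, pmax(-1, u))
    p <- 50 * acos(u) / pi
    if (extension) 100 - p else p
  }

  for (k in seq_len(n_cyc)) {
    i0 <- seg$ext_peak_idx[k]
    i2 <- seg$ext_peak_idx[k + 1L]
    fl <- seg$flex_peak_idx[seg$flex_peak_idx > i0 & seg$flex_peak_idx < i2]
    info$t_start[k] <- t[i0]; info$t_end[k] <- t[i2]
    info$duration[k] <- t[i2] - t[i0]
    if (length(fl) != 1L) { info$excluded[k] <- TRUE; next }
    i1 <- fl
    A_e <- th[i0]; A_f <- th[i1]; A_e2 <- th[i2]
    if (A_e == A_f || A_e2 == A_f) { info$excluded[k] <- TRUE; next }
    ix_f <- i0:(i1 - 1L)
    ix_e <- i1:(i2 - 1L)
    phase[ix_f] <- half_phase(ix_f, A_e, A_f, extension = FALSE)
    phase[ix_e] <- half_phase(ix_e, A_e2, A_f, extension = TRUE)
    cycle_id[c(ix_f, ix_e)] <- k
  }
  # closing boundary sample of the recording belongs to the last cycle
  i_last <- seg$ext_peak_idx[n_cyc + 1L]
  if (is.na(cycle_id[i_last]) && !info$excluded[n_cyc]) {
    phase[i_last] <- 100
    cycle_id[i_last] <- n_cyc
  }
  structure(data.frame(t = t, phase = phase, cycle_id = cycle_id),
            cycles = info,
            class = c("baseline_phase", "data.frame"))
}

#' @export
print.baseline_phase <- function(x, ...) {
  info <- attr(x, "cycles")
  cat(sprintf("baseline_phase: %d samples, %d cycles (%d excluded)\n",
              nrow(x), nrow(info), sum(info$excluded)))
  invisible(x)
}

#' Extract target events from the baseline phase
#'
#' The stimulation-trigger targets are the times at which the baseline phase
#' first crosses each threshold level within a cycle — by default 10, 40, 60
#' and 90%, i.e. +/-10% of the cycle around the flexion and extension peaks.
#' Crossing times are linearly interpolated between bracketing samples. A
#' complete, non-excluded cycle yields exactly one event per level; a cycle
#' that never reaches a level yields no event for it and a warning.
#'
#' @param phase A [compute_baseline_phase()] result.
#' @param levels Threshold levels in percent, each strictly inside (0, 100).
#' @return Data frame with columns `source` (`"baseline"`), `cycle_id`,
#'   `level_pct`, `time_s`, `cycle_duration_s`, ordered by cycle then level.
#' @export
extract_target_events <- function(phase, levels = c(10, 40, 60, 90)) {
  stopifnot(inherits(phase, "baseline_phase"))
  if (any(levels <= 0 | levels >= 100)) {
    stop("extract_target_events: levels must lie strictly inside (0, 100)",
         call. = FALSE)
  }
  info <- attr(phase, "cycles")
  out <- list()
  for (k in info$cycle_id[!info$excluded]) {
    sel <- which(phase$cycle_id == k)
    if (length(sel) < 2L) next
    p <- phase$phase[sel]
    tt <- phase$t[sel]
    dur <- info$duration[info$cycle_id == k]
    for (L in sort(levels)) {
      j <- which(p[-length(p)] < L & p[-1L] >= L)
      if (length(j) == 0L) {
        if (p[1L] >= L) j <- 0L  # level already passed at cycle start
        else {
          warning(sprintf("cycle %d never reaches level %g%%", k, L))
          next
        }
      }
      j <- j[1L]
      time <- if (j == 0L) tt[1L] else {
        tt[j] + (L - p[j]) / (p[j + 1L] - p[j]) * (tt[j + 1L] - tt[j])
      }
      out[[length(out) + 1L]] <- data.frame(source = "baseline", cycle_id = k,
                                            level_pct = L, time_s = time,
                                            cycle_duration_s = dur)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(source = character(), cycle_id = integer(),
                      level_pct = numeric(), time_s = numeric(),
                      cycle_duration_s = numeric()))
  }
  do.call(rbind, out)
}
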