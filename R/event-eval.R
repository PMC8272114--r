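#' Pair detected events with baseline targets
#'
#' Greedy nearest-in-time matching within each level. Each detection is
#' assigned to its nearest same-level target provided the gap does not exceed
#' `window_cycles` times that target's cycle duration. The closest detection
#' per target is its primary match; surplus same-level detections assigned to
#' an already-matched target are kept as false positives — they penalise the
#' detector in the delay statistics rather than being silently dropped.
#' Detections farther than the window from any same-level target are excluded
#' and counted; targets with no detection in the window are false negatives
#' (no delay can be recorded for them). Delays are signed and normalised to
#' the duration of the target's own cycle, so a uniform cadence change leaves
#' them untouched: `delay_pct = 100 * (detected - target) / cycle_duration`
#' (negative = early, positive = late).
#'
#' @param detected Data frame of detections (`source`, `level_pct`, `time_s`,
#'   optional `warmup`), one source per call or several.
#' @param targets Data frame from [extract_target_events()].
#' @param window_cycles Matching window as a multiple of the target's cycle
#'   duration. Default 1.0.
#' @param include_warmup Keep detections flagged `warmup`. Default `TRUE`
#'   (penalty philosophy: a detector answers for everything it emits).
#' @return List with elements:
#'   \describe{
#'     \item{paired}{data frame `source`, `level_pct`, `target_time_s`,
#'       `detected_time_s`, `cycle_duration_s`, `delay_pct`,
#'       `is_false_positive`;}
#'     \item{ledger}{data frame, one row per source: `n_paired`,
#'       `n_false_positive`, `n_false_negative`, `n_excluded`, satisfying
#'       `n_paired = n_targets - n_false_negative + n_false_positive`.}
#'   }
#' @export
pair_events <- function(detected, targets, window_cycles = 1.0,
                        include_warmup = TRUE) {
  if (is.null(targets) || nrow(targets) == 0L) {
    stop("pair_events: no baseline", call. = FALSE)
  }
  detected <- as.data.frame(detected)
  if (!include_warmup && "warmup" %in% names(detected)) {
    detected <- detected[!detected$warmup, , drop = FALSE]
  }
  sources <- unique(detected$source)
  paired <- list()
  ledger <- list()
  for (src in sources) {
    n_fp <- 0L; n_fn <- 0L; n_excl <- 0L
    for (L in sort(unique(targets$level_pct))) {
      tg <- targets[targets$level_pct == L, , drop = FALSE]
      tg <- tg[order(tg$time_s), , drop = FALSE]
      de <- detected[detected$source == src & detected$level_pct == L, ,
                     drop = FALSE]
      de <- de[order(de$time_s), , drop = FALSE]
      if (nrow(de) == 0L) { n_fn <- n_fn + nrow(tg); next }
      nearest <- vapply(de$time_s,
                        function(x) which.min(abs(tg$time_s - x)), 1L)
      gap <- abs(de$time_s - tg$time_s[nearest])
      ok <- gap <= window_cycles * tg$cycle_duration_s[nearest]
      n_excl <- n_excl + sum(!ok)
      de <- de[ok, , drop = FALSE]
      nearest <- nearest[ok]; gap <- gap[ok]
      primary <- rep(FALSE, nrow(de))
      for (ti in unique(nearest)) {
        cand <- which(nearest == ti)
        primary[cand[which.min(gap[cand])]] <- TRUE
      }
      n_fp <- n_fp + sum(!primary)
      n_fn <- n_fn + nrow(tg) - length(unique(nearest))
      if (nrow(de) > 0L) {
        dur <- tg$cycle_duration_s[nearest]
        paired[[length(paired) + 1L]] <- data.frame(
          source = src, level_pct = L,
          target_time_s = tg$time_s[nearest],
          detected_time_s = de$time_s,
          cycle_duration_s = dur,
          delay_pct = 100 * (de$time_s - tg$time_s[nearest]) / dur,
          is_false_positive = !primary)
      }
    }
    n_paired <- sum(vapply(paired, function(p) sum(p$source == src), 0L))
    ledger[[length(ledger) + 1L]] <- data.frame(
      source = src, n_paired = n_paired, n_false_positive = n_fp,
      n_false_negative = n_fn, n_excluded = n_excl)
  }
  paired_df <- if (length(paired) > 0L) do.call(rbind, paired) else {
    data.frame(source = character(), level_pct = numeric(),
               target_time_s = numeric(), detected_time_s = numeric(),
               cycle_duration_s = numeric(), delay_pct = numeric(),
               is_false_positive = logical())
  }
  paired_df <- paired_df[order(paired_df$source, paired_df$detected_time_s), ,
                         drop = FALSE]
  rownames(paired_df) <- NULL
  list(paired = paired_df, ledger = do.call(rbind, ledger))
}

#' Convert a normalised delay to milliseconds at a given cadence
#'
#' `ms = delay_pct / 100 * (60 / cadence_rpm) * 1000`. For example +10% of a
#' 60 RPM cycle is 100 ms, and -0.40% at 24.1 RPM is about -10 ms.
#'
#' @param delay_pct Signed delay in percent of cycle duration.
#' @param cadence_rpm Cadence in revolutions per minute (> 0).
#' @return Delay in milliseconds.
#' @export
delay_to_ms <- function(delay_pct, cadence_rpm) {
  stopifnot(all(cadence_rpm > 0))
  delay_pct / 100 * (60 / cadence_rpm) * 1000
}

#' Express a sampling period as a percentage of the cycle at a cadence
#'
#' A 16 ms sampling period at 60 RPM spans 1.6% of the cycle; a 1 ms period
#' (1000 Hz) spans 0.1%.
#'
#' @param period_s Sampling period in seconds.
#' @param cadence_rpm Cadence in revolutions per minute (> 0).
#' @return Percentage of the cycle duration.
#' @export
period_to_cycle_pct <- function(period_s, cadence_rpm) {
  stopifnot(all(cadence_rpm > 0))
  period_s / (60 / cadence_rpm) * 100
}
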