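#' Simulate a recording and persist it
#'
#' Runs the synthetic-motion generator and writes the angle series, the
#' ground-truth phase, the ground-truth peak table and a manifest recording
#' the spec, seed and package version. Reruns with the same spec are
#' bit-identical.
#'
#' @param spec A [motion_spec()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the list from [generate_motion()] with a `files`
#'   element naming the written paths.
#' @export
simulate_recording <- function(spec, out_dir) {
  stopifnot(inherits(spec, "motion_spec"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim <- generate_motion(spec)
  f_angle <- file.path(out_dir, "angle.csv")
  f_phase <- file.path(out_dir, "truth_phase.csv")
  f_peaks <- file.path(out_dir, "truth_peaks.csv")
  f_manifest <- file.path(out_dir, "manifest.txt")
  write_angle_csv(sim$series, f_angle)
  utils::write.csv(data.frame(time_s = fmt_num(sim$series$t),
                              true_phase_pct = fmt_num(sim$truth$true_phase)),
                   f_phase, row.names = FALSE, quote = FALSE)
  peaks <- rbind(data.frame(kind = "ext", time_s = sim$truth$ext_peak_times),
                 data.frame(kind = "flex", time_s = sim$truth$flex_peak_times))
  peaks <- peaks[order(peaks$time_s), ]
  utils::write.csv(data.frame(kind = peaks$kind, time_s = fmt_num(peaks$time_s)),
                   f_peaks, row.names = FALSE, quote = FALSE)
  fields <- unlist(spec)
  writeLines(c(sprintf("pedalphase_version=%s",
                       as.character(utils::packageVersion("pedalphase"))),
               paste0(names(fields), "=", fields)),
             f_manifest)
  sim$files <- c(angle = f_angle, phase = f_phase, peaks = f_peaks,
                 manifest = f_manifest)
  invisible(sim)
}

#' Evaluate event detectors against the baseline reference on one recording
#'
#' End-to-end pipeline: upsample the recording to a uniform grid (1000 Hz by
#' default), segment cycles, compute the linearised baseline phase and its
#' target events, run the requested estimators, extract their detections,
#' pair detections with targets, and compute the agreement layer
#' (non-parametric limits of agreement with the accepted-margin criterion,
#' and Lin's concordance coefficient with McBride class on target-versus-
#' detected phase pairs).
#'
#' The Hilbert phase is rotated by -50 points before event extraction: the
#' analytic-signal argument is 0 at the signal maximum, whereas the cycle
#' convention puts the extension peak (signal maximum) at phase 0.
#'
#' @param input An [angle_series()] or a path to an angle CSV.
#' @param estimators Subset of `c("bsgonio", "hilbert", "gci")`.
#' @param levels Target levels in percent. Default `c(10, 40, 60, 90)`.
#' @param margin_pct Accepted error margin. Default 10.
#' @param fs Uniform grid frequency in Hz. Default 1000.
#' @param bsgonio,gci Parameter objects for the two online estimators.
#' @param window_cycles Pairing window (multiples of cycle duration).
#' @param include_warmup Keep warm-up detections. Default `TRUE`.
#' @param out_dir If non-`NULL`, persist every stage (events, paired delays,
#'   report, plot data) as CSV under this directory.
#' @return List with `targets`, `events`, `paired`, `ledger`, `report`
#'   (one row per estimator: delay summary, LoA, criterion, CCC, CI,
#'   McBride class) and `plot_data` (per-event rows for Bland-Altman and
#'   concordance plots).
#' @export
evaluate_recording <- function(input,
                               estimators = c("bsgonio", "hilbert", "gci"),
                               levels = c(10, 40, 60, 90),
                               margin_pct = 10, fs = 1000,
                               bsgonio = bsgonio_params(),
                               gci = gci_params(),
                               window_cycles = 1.0,
                               include_warmup = TRUE,
                               out_dir = NULL) {
  estimators <- match.arg(estimators, c("bsgonio", "hilbert", "gci"),
                          several.ok = TRUE)
  series <- if (inherits(input, "angle_series")) input else read_angle_csv(input)
  uni <- upsample_linear(series, fs = fs)
  seg <- segment_cycles(uni)
  base <- compute_baseline_phase(uni, seg)
  targets <- suppressWarnings(extract_target_events(base, levels))
  if (nrow(targets) == 0L) stop("evaluate_recording: no complete cycles",
                                call. = FALSE)

  ev <- list()
  if ("bsgonio" %in% estimators) {
    ev$bsgonio <- run_bsgonio(uni, bsgonio)
  }
  if ("hilbert" %in% estimators) {
    ev$hilbert <- phase_to_events(rotate_phase(hilbert_phase(uni), -50),
                                  levels)
  }
  if ("gci" %in% estimators) {
    ev$gci <- phase_to_events(run_gci_observer(uni, gci), levels)
  }
  events <- do.call(rbind, unname(ev))
  pr <- pair_events(events, targets, window_cycles = window_cycles,
                    include_warmup = include_warmup)
  rep <- report_agreement(pr$paired, margin_pct = margin_pct)

  out <- list(targets = targets, events = events, paired = pr$paired,
              ledger = pr$ledger, report = rep$report,
              plot_data = rep$plot_data)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    tg <- data.frame(source = targets$source, level_pct = targets$level_pct,
                     time_s = targets$time_s, cycle_id = targets$cycle_id)
    write_events_csv(tg, file.path(out_dir, "targets.csv"))
    write_events_csv(data.frame(source = events$source,
                                level_pct = events$level_pct,
                                time_s = events$time_s),
                     file.path(out_dir, "detected.csv"))
    utils::write.csv(pr$paired, file.path(out_dir, "paired_delays.csv"),
                     row.names = FALSE)
    utils::write.csv(pr$ledger, file.path(out_dir, "ledger.csv"),
                     row.names = FALSE)
    utils::write.csv(out$report, file.path(out_dir, "report.csv"),
                     row.names = FALSE)
    utils::write.csv(rep$plot_data$bland_altman,
                     file.path(out_dir, "bland_altman_data.csv"),
                     row.names = FALSE)
    utils::write.csv(rep$plot_data$concordance,
                     file.path(out_dir, "concordance_data.csv"),
                     row.names = FALSE)
  }
  out
}

#' Recompute the agreement layer from a paired-delay table
#'
#' Takes the paired-delay table (as produced by [pair_events()] or read back
#' from its CSV) and recomputes, per source: the delay summary with
#' non-parametric LoA and the margin criterion, and Lin's CCC with its 95%
#' CI and McBride class on (target level, target level + delay) pairs in
#' percent-of-cycle units. Also returns per-event plot data for
#' Bland-Altman (delay vs target level, with LoA and margin lines) and
#' concordance (target vs detected phase) displays.
#'
#' @param paired Data frame with at least `source`, `level_pct`,
#'   `delay_pct`.
#' @param margin_pct Accepted error margin. Default 10.
#' @return List with `report` (one row per source) and `plot_data` (list of
#'   data frames `bland_altman`, `concordance`).
#' @export
report_agreement <- function(paired, margin_pct = 10) {
  paired <- as.data.frame(paired)
  if (nrow(paired) == 0L) stop("report_agreement: empty paired-delay table",
                               call. = FALSE)
  need <- c("source", "level_pct", "delay_pct")
  if (!all(need %in% names(paired))) {
    stop(sprintf("report_agreement: missing columns: %s",
                 paste(setdiff(need, names(paired)), collapse = ", ")),
         call. = FALSE)
  }
  summ <- summarize_delays(paired, margin_pct)
  ccc <- lapply(summ$source, function(src) {
    d <- paired[paired$source == src, ]
    cc <- lins_ccc(d$level_pct, d$level_pct + d$delay_pct)
    data.frame(ccc = cc$rho_c, ccc_ci_low = cc$ci_low,
               ccc_ci_high = cc$ci_high, mcbride = cc$mcbride_class)
  })
  report <- cbind(summ, do.call(rbind, ccc))

  ba <- data.frame(source = paired$source, level_pct = paired$level_pct,
                   delay_pct = paired$delay_pct)
  ba <- merge(ba, summ[, c("source", "lower_loa_pct", "upper_loa_pct",
                           "median_pct")], by = "source")
  ba$margin_lower <- -margin_pct
  ba$margin_upper <- margin_pct
  conc <- data.frame(source = paired$source, level_pct = paired$level_pct,
                     target_phase_pct = paired$level_pct,
                     detected_phase_pct = paired$level_pct + paired$delay_pct)
  list(report = report, plot_data = list(bland_altman = ba,
                                         concordance = conc))
}
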