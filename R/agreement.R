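#' Normality gate for delay distributions
#'
#' Shapiro-Wilk test on the delays at significance level `alpha`. When any
#' estimator's delays fail the gate, the agreement layer reports the
#' non-parametric limits of agreement (percentiles) rather than the
#' mean +/- 1.96 SD form.
#'
#' @param delays Numeric vector, 3 <= n <= 5000, non-constant.
#' @param alpha Significance level. Default 0.05.
#' @return List with `p_value` and `is_normal` (`p_value >= alpha`).
#' @export
shapiro_gate <- function(delays, alpha = 0.05) {
  delays <- as.numeric(delays)
  n <- length(delays)
  if (n < 3L || n > 5000L) {
    stop("shapiro_gate: need 3 <= n <= 5000", call. = FALSE)
  }
  if (diff(range(delays)) == 0) {
    stop("shapiro_gate: constant sample", call. = FALSE)
  }
  p <- stats::shapiro.test(delays)$p.value
  list(p_value = p, is_normal = p >= alpha)
}

# 2.5/97.5 (and other) percentiles by linear interpolation of order
# statistics at rank position (n - 1) * q + 1 — stats::quantile type 7
pct_interp <- function(x, q) unname(stats::quantile(x, q, type = 7))

#' Non-parametric Bland-Altman limits of agreement
#'
#' The 95% limits of agreement are the 2.5th and 97.5th percentiles of the
#' delay distribution, computed by linear interpolation of order statistics
#' at rank position `(n - 1) * q + 1`. The acceptance criterion passes when
#' both limits lie inside the accepted error margin (default +/-10% of cycle
#' duration, i.e. 100 ms at the 60 RPM upper end of FES-cycling cadence) —
#' equivalently, when at least 95% of delays fall inside the margin.
#' `abs_loa_pct` is reported as the 95th percentile of `|delay|` (this
#' package's definition of a single-sided absolute limit).
#'
#' @param delays Numeric vector of normalised delays in percent of cycle
#'   duration. A warning is issued below n = 40, where the outer percentiles
#'   are poorly determined.
#' @param margin_pct Accepted error margin in percent. Default 10.
#' @return An object of class `loa_result`: list with `n`, `median_pct`,
#'   `mean_pct`, `sd_pct`, `lower_loa_pct`, `upper_loa_pct`, `abs_loa_pct`,
#'   `margin_pct`, `criterion_pass`.
#' @export
nonparametric_loa <- function(delays, margin_pct = 10) {
  delays <- as.numeric(delays)
  n <- length(delays)
  if (n == 0L) stop("nonparametric_loa: empty input", call. = FALSE)
  if (n < 40L) {
    warning("nonparametric_loa: fewer than 40 delays; 2.5/97.5 percentiles are poorly determined")
  }
  lower <- pct_interp(delays, 0.025)
  upper <- pct_interp(delays, 0.975)
  structure(list(n = n,
                 median_pct = stats::median(delays),
                 mean_pct = mean(delays),
                 sd_pct = stats::sd(delays),
                 lower_loa_pct = lower,
                 upper_loa_pct = upper,
                 abs_loa_pct = pct_interp(abs(delays), 0.95),
                 margin_pct = margin_pct,
                 criterion_pass = (lower >= -margin_pct) && (upper <= margin_pct)),
            class = "loa_result")
}

#' Parametric Bland-Altman limits of agreement
#'
#' The classical `mean +/- 1.96 * SD` limits, for use when the normality gate
#' passes. Provided for completeness; the default pipeline path is
#' [nonparametric_loa()].
#'
#' @inheritParams nonparametric_loa
#' @return An object of class `loa_result` (same fields; LoA from the
#'   parametric formula, `abs_loa_pct` as in [nonparametric_loa()]).
#' @export
parametric_loa <- function(delays, margin_pct = 10) {
  delays <- as.numeric(delays)
  if (length(delays) == 0L) stop("parametric_loa: empty input", call. = FALSE)
  m <- mean(delays); s <- stats::sd(delays)
  lower <- m - 1.96 * s
  upper <- m + 1.96 * s
  structure(list(n = length(delays),
                 median_pct = stats::median(delays),
                 mean_pct = m, sd_pct = s,
                 lower_loa_pct = lower, upper_loa_pct = upper,
                 abs_loa_pct = pct_interp(abs(delays), 0.95),
                 margin_pct = margin_pct,
                 criterion_pass = (lower >= -margin_pct) && (upper <= margin_pct)),
            class = "loa_result")
}

#' @export
print.loa_result <- function(x, ...) {
  cat(sprintf("limits of agreement (n = %d):\n", x$n))
  cat(sprintf("  median %+.2f  mean %+.2f +/- %.2f %% of cycle\n",
              x$median_pct, x$mean_pct, x$sd_pct))
  cat(sprintf("  95%% LoA [%+.2f, %+.2f], |delay| 95th pct %.2f\n",
              x$lower_loa_pct, x$upper_loa_pct, x$abs_loa_pct))
  cat(sprintf("  criterion (+/-%g%%): %s\n", x$margin_pct,
              if (x$criterion_pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Lin's concordance correlation coefficient
#'
#' Measures agreement with the identity line: the product of the Pearson
#' correlation (precision) and a bias-correction factor penalising location
#' and scale shifts (accuracy). With population (n-denominator) moments,
#' `rho_c = 2 * s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)`.
#' The 95% confidence interval uses the Fisher z-transform with Lin's (1989)
#' asymptotic variance, back-transformed. Always `rho_c <= |r|`.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, each non-constant.
#' @param conf_level Confidence level. Default 0.95.
#' @return An object of class `ccc_result`: list with `rho_c`, `ci_low`,
#'   `ci_high`, `n`, `mcbride_class` (see [mcbride_class()]).
#' @examples
#' lins_ccc(c(1, 2, 3), c(2, 3, 4))$rho_c  # 4/7
#' @export
lins_ccc <- function(x, y, conf_level = 0.95) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("lins_ccc: unequal lengths", call. = FALSE)
  if (n < 3L) stop("lins_ccc: need n >= 3", call. = FALSE)
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    stop("lins_ccc: constant input", call. = FALSE)
  }
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  rho_c <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- sxy / sqrt(sx2 * sy2)
  if (abs(rho_c) >= 1 - 1e-15) {
    ci <- c(rho_c, rho_c)
  } else {
    u <- (mx - my) / (sx2 * sy2)^0.25
    var_z <- ((1 - r^2) * rho_c^2 / ((1 - rho_c^2) * r^2) +
              2 * rho_c^3 * (1 - rho_c) * u^2 / (r * (1 - rho_c^2)^2) -
              rho_c^4 * u^4 / (2 * r^2 * (1 - rho_c^2)^2)) / (n - 2)
    z <- atanh(rho_c)
    half <- stats::qnorm(1 - (1 - conf_level) / 2) * sqrt(var_z)
    ci <- tanh(c(z - half, z + half))
  }
  structure(list(rho_c = rho_c, ci_low = ci[1L], ci_high = ci[2L], n = n,
                 mcbride_class = mcbride_class(ci[1L])),
            class = "ccc_result")
}

#' @export
print.ccc_result <- function(x, ...) {
  cat(sprintf("Lin's CCC: %.4f (95%% CI %.4f-%.4f, n = %d) -> %s\n",
              x$rho_c, x$ci_low, x$ci_high, x$n, x$mcbride_class))
  invisible(x)
}

#' McBride strength-of-agreement class
#'
#' Classifies the lower one-sided 95% confidence limit of Lin's CCC:
#' below 0.90 poor, 0.90 to < 0.95 moderate, 0.95 to < 0.99 substantial,
#' 0.99 and above almost perfect.
#'
#' @param ci_low Lower confidence limit, in `[-1, 1]`.
#' @return One of `"poor"`, `"moderate"`, `"substantial"`,
#'   `"almost perfect"`.
#' @export
mcbride_class <- function(ci_low) {
  stopifnot(ci_low >= -1, ci_low <= 1)
  if (ci_low < 0.90) "poor"
  else if (ci_low < 0.95) "moderate"
  else if (ci_low < 0.99) "substantial"
  else "almost perfect"
}

#' Construct balanced target/detection pairs with given delay moments
#'
#' Builds the minimal paired data set on which agreement statistics with
#' prescribed delay moments can be computed exactly: targets `x` take the
#' threshold levels equally often, and each level receives the two delays
#' `mean_delay +/- sd_delay`, so the sample delay mean is `mean_delay`, the
#' population delay SD is `sd_delay`, and the in-sample delay-target
#' correlation is zero. Useful for reconstructing a concordance coefficient
#' from reported delay moments.
#'
#' @param mean_delay,sd_delay Delay moments in percent of cycle duration.
#' @param levels Target levels in percent. Default `c(10, 40, 60, 90)`.
#' @param per_level Even number of points per level. Default 2.
#' @return Data frame with columns `x` (target) and `y` (detection,
#'   `x + delay`).
#' @export
balanced_target_pairs <- function(mean_delay, sd_delay,
                                  levels = c(10, 40, 60, 90), per_level = 2L) {
  stopifnot(per_level >= 2L, per_level %% 2L == 0L)
  x <- rep(levels, each = per_level)
  d <- rep(c(mean_delay + sd_delay, mean_delay - sd_delay),
           length.out = length(x))
  data.frame(x = x, y = x + d)
}

#' Per-estimator delay summary
#'
#' One row per source with the reporting set used for method comparison:
#' number of paired events, median, mean and SD (n-1 denominator) of the
#' normalised delays, non-parametric 95% LoA, the 95th percentile of the
#' absolute delay, and the margin criterion verdict.
#'
#' @param paired The `paired` data frame from [pair_events()] (column
#'   `delay_pct` grouped by `source`).
#' @param margin_pct Accepted error margin in percent. Default 10.
#' @return Data frame, one row per source.
#' @export
summarize_delays <- function(paired, margin_pct = 10) {
  paired <- as.data.frame(paired)
  if (nrow(paired) == 0L) stop("summarize_delays: empty input", call. = FALSE)
  rows <- lapply(unique(paired$source), function(src) {
    d <- paired$delay_pct[paired$source == src]
    loa <- suppressWarnings(nonparametric_loa(d, margin_pct))
    data.frame(source = src, n = loa$n, median_pct = loa$median_pct,
               mean_pct = loa$mean_pct, sd_pct = loa$sd_pct,
               lower_loa_pct = loa$lower_loa_pct,
               upper_loa_pct = loa$upper_loa_pct,
               abs_loa_pct = loa$abs_loa_pct,
               criterion_pass = loa$criterion_pass)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
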