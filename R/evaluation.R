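# Validation harness: modeled-vs-measured statistics, residual-trend
# detection, percentile exceedance, the Dutch Social Economic Council (SEC)
# acceptance criteria, and tier-conservatism checks.

#' Paired predicted/measured comparison set
#'
#' @param predicted,measured Positive concentration vectors
#'   (mg m\eqn{^{-3}}), equal length >= 1.
#' @param scenario Optional scenario identifiers.
#' @param flavour What the prediction is: `"gm"`, `"percentile"` or
#'   `"percentile_ucl"` (percentile with an upper confidence bound).
#' @return A data frame of class `comparison_set`.
#' @export
comparison_set <- function(predicted, measured, scenario = NULL,
                           flavour = c("gm", "percentile",
                                       "percentile_ucl")) {
  flavour <- match.arg(flavour)
  if (length(predicted) != length(measured) || length(predicted) < 1) {
    stop("predicted and measured must have equal length >= 1")
  }
  if (any(!is.finite(predicted) | predicted <= 0) ||
      any(!is.finite(measured) | measured <= 0)) {
    stop("all predicted and measured concentrations must be positive")
  }
  if (is.null(scenario)) scenario <- sprintf("s%04d", seq_along(predicted))
  structure(data.frame(scenario = scenario, predicted = predicted,
                       measured = measured, stringsAsFactors = FALSE),
            class = c("comparison_set", "data.frame"),
            flavour = flavour)
}

#' Ratio statistics of a comparison set
#'
#' Summarizes the predicted/measured ratios: geometric-mean ratio, the
#' ratio range (max ratio / min ratio — the "spread over N orders of
#' magnitude" figure of merit), and the fractions of comparisons within a
#' factor of 2 and of 10.
#'
#' @param c A [comparison_set()].
#' @return A list of class `ratio_stats` with elements `gm_ratio`,
#'   `ratio_range`, `within_factor2`, `within_factor10`, `n`.
#' @export
ratio_stats <- function(c) {
  stopifnot(inherits(c, "comparison_set"))
  r <- c$predicted / c$measured
  structure(list(gm_ratio = exp(mean(log(r))),
                 ratio_range = max(r) / min(r),
                 within_factor2 = mean(abs(log(r)) <= log(2)),
                 within_factor10 = mean(abs(log(r)) <= log(10)),
                 n = length(r)),
            class = "ratio_stats")
}

#' @export
print.ratio_stats <- function(x, ...) {
  cat("<ratio_stats> n =", x$n, "\n")
  cat(sprintf("  GM(pred/meas) = %.3g, ratio range = %.3g\n",
              x$gm_ratio, x$ratio_range))
  cat(sprintf("  within x2: %.1f%%, within x10: %.1f%%\n",
              100 * x$within_factor2, 100 * x$within_factor10))
  invisible(x)
}

#' Pearson and Spearman correlation of a comparison set
#'
#' Computed on ln-transformed pairs by default (validation studies report
#' correlations for log-transformed data); Spearman uses midranks for ties.
#'
#' @param c A [comparison_set()].
#' @param log_scale Transform to natural logs first (default `TRUE`).
#' @return List with `pearson`, `spearman`, `n`, and `degenerate` (`TRUE`
#'   when either channel has zero variance, in which case the coefficients
#'   are `NA`).
#' @export
correlation_summary <- function(c, log_scale = TRUE) {
  stopifnot(inherits(c, "comparison_set"))
  if (nrow(c) < 3) stop("need at least 3 pairs for a correlation")
  x <- c$predicted; y <- c$measured
  if (log_scale) { x <- log(x); y <- log(y) }
  degenerate <- stats::var(x) == 0 || stats::var(y) == 0
  if (degenerate) {
    return(list(pearson = NA_real_, spearman = NA_real_, n = nrow(c),
                degenerate = TRUE))
  }
  list(pearson = stats::cor(x, y, method = "pearson"),
       spearman = stats::cor(x, y, method = "spearman"),
       n = nrow(c), degenerate = FALSE)
}

#' Detect a systematic residual trend
#'
#' Regresses the log-scale residual (ln predicted - ln measured) on
#' ln measured. A significantly negative slope is the "overestimate low
#' exposures, underestimate high exposures" pattern: the trend flag is set
#' when the slope is negative and its confidence interval excludes zero.
#'
#' @param c A [comparison_set()].
#' @param conf Confidence level for the slope interval (default 0.95).
#' @return List of class `residual_trend` with `slope`, `ci` (length 2),
#'   `flag`, `n`.
#' @export
residual_trend <- function(c, conf = 0.95) {
  stopifnot(inherits(c, "comparison_set"))
  if (nrow(c) < 3) stop("need at least 3 pairs for a residual trend")
  resid <- log(c$predicted) - log(c$measured)
  x <- log(c$measured)
  if (stats::var(x) == 0) stop("measured channel has zero variance")
  fit <- stats::lm(resid ~ x)
  slope <- unname(stats::coef(fit)[2])
  if (stats::var(resid) < .Machine$double.eps * max(1, mean(resid)^2)) {
    # constant residual: pure bias, exactly no trend
    slope <- 0
    ci <- c(0, 0)
  } else {
    # an exactly linear relation triggers lm's perfect-fit warning;
    # the degenerate ci is handled below
    ci <- unname(suppressWarnings(
      stats::confint(fit, "x", level = conf))[1, ])
    if (any(!is.finite(ci))) ci <- c(slope, slope)
  }
  structure(list(slope = slope, ci = ci,
                 flag = slope < 0 && ci[2] < 0, n = nrow(c)),
            class = "residual_trend")
}

#' @export
print.residual_trend <- function(x, ...) {
  cat(sprintf("<residual_trend> slope = %.3g [%.3g, %.3g], flag = %s\n",
              x$slope, x$ci[1], x$ci[2], x$flag))
  invisible(x)
}

#' Fraction of measurements exceeding the model estimate
#'
#' Intended for percentile-type (precautionary) predictions: the fraction
#' of pairs in which the measured concentration exceeds the predicted
#' estimate. Invariant under any strictly increasing rescaling applied to
#' both channels.
#'
#' @param c A [comparison_set()].
#' @return Fraction in \[0, 1\].
#' @export
exceedance_fraction <- function(c) {
  stopifnot(inherits(c, "comparison_set"))
  mean(c$measured > c$predicted)
}

#' Dutch SEC acceptance criteria check
#'
#' Applies the regulatory acceptance criteria for exposure models: at least
#' 20 comparisons per application domain, Spearman correlation (on
#' log-transformed data by default) of at least 0.6, and measurements
#' exceeding the model estimates in at most 10% of comparisons. The
#' "reasonable worst-case" criterion has no operational definition; it is
#' reported as an advisory flag equal to the exceedance criterion, never as
#' an independent numeric test. The overall verdict is exactly the
#' conjunction of the three operational criteria.
#'
#' @param c A [comparison_set()].
#' @param log_scale Compute the Spearman correlation on natural-log data
#'   (default `TRUE`).
#' @return A list of class `criteria_result`: `n_comparisons`,
#'   `spearman_r`, `exceedance_fraction`, `criteria` (named logicals
#'   `n_ge_20`, `spearman_ge_0.6`, `exceedance_le_0.10`),
#'   `worst_case_advisory`, `overall_pass`.
#' @export
sec_criteria_check <- function(c, log_scale = TRUE) {
  stopifnot(inherits(c, "comparison_set"))
  n <- nrow(c)
  r <- if (n >= 3) correlation_summary(c, log_scale)$spearman else NA_real_
  ex <- exceedance_fraction(c)
  crit <- c(n_ge_20 = n >= 20,
            spearman_ge_0.6 = !is.na(r) && r >= 0.6,
            exceedance_le_0.10 = ex <= 0.10)
  structure(list(n_comparisons = n, spearman_r = r,
                 exceedance_fraction = ex, criteria = crit,
                 worst_case_advisory = unname(crit["exceedance_le_0.10"]),
                 overall_pass = all(crit)),
            class = "criteria_result")
}

#' @export
print.criteria_result <- function(x, ...) {
  cat("<criteria_result>\n")
  cat(sprintf("  n = %d, Spearman(ln) = %s, exceedance = %.1f%%\n",
              x$n_comparisons,
              ifelse(is.na(x$spearman_r), "NA",
                     sprintf("%.3f", x$spearman_r)),
              100 * x$exceedance_fraction))
  for (nm in names(x$criteria)) {
    cat(sprintf("  %-20s %s\n", nm,
                ifelse(x$criteria[nm], "PASS", "FAIL")))
  }
  cat("  overall:", ifelse(x$overall_pass, "PASS", "FAIL"), "\n")
  invisible(x)
}

#' Tier-conservatism check
#'
#' In a tiered assessment a lower tier must always yield a higher (more
#' precautionary) exposure estimate. Flags every inversion (a higher tier
#' exceeding a lower tier) and, when a measured value is supplied, every
#' tier whose estimate falls below the measurement.
#'
#' @param estimates Named numeric vector of predicted concentrations; names
#'   are tier labels ordered or parseable as increasing tier level (e.g.
#'   `c(tier1 = 10, tier2 = 5)`). Order of the vector defines tier order,
#'   lowest tier first.
#' @param measured Optional measured concentration.
#' @return List of class `tier_report`: `inversions` (data frame of
#'   offending tier pairs), `underestimating_tiers` (character), `pass`.
#' @export
tier_conservatism_check <- function(estimates, measured = NULL) {
  if (length(estimates) < 2) stop("need at least two tiers")
  if (is.null(names(estimates))) {
    names(estimates) <- paste0("tier", seq_along(estimates))
  }
  inv <- list()
  for (i in seq_len(length(estimates) - 1)) {
    for (j in seq(i + 1, length(estimates))) {
      if (estimates[j] > estimates[i]) {
        inv[[length(inv) + 1]] <- data.frame(
          lower_tier = names(estimates)[i],
          higher_tier = names(estimates)[j],
          lower_estimate = unname(estimates[i]),
          higher_estimate = unname(estimates[j]),
          stringsAsFactors = FALSE)
      }
    }
  }
  inversions <- if (length(inv) > 0) do.call(rbind, inv) else
    data.frame(lower_tier = character(), higher_tier = character(),
               lower_estimate = numeric(), higher_estimate = numeric(),
               stringsAsFactors = FALSE)
  under <- character()
  if (!is.null(measured)) {
    under <- names(estimates)[estimates < measured]
  }
  structure(list(inversions = inversions,
                 underestimating_tiers = under,
                 pass = nrow(inversions) == 0 && length(under) == 0),
            class = "tier_report")
}

#' @export
print.tier_report <- function(x, ...) {
  cat("<tier_report>", ifelse(x$pass, "PASS", "FAIL"), "\n")
  if (nrow(x$inversions) > 0) {
    cat("  tier inversions:\n")
    print.data.frame(x$inversions, row.names = FALSE)
  }
  if (length(x$underestimating_tiers) > 0) {
    cat("  tiers below the measured value:",
        paste(x$underestimating_tiers, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Log-symmetric accuracy interval around a central concentration
#'
#' Converts a "ratio range of R" accuracy statement into the log-symmetric
#' concentration interval it implies around a central value:
#' \eqn{[c/\sqrt{R},\; c\sqrt{R}]}. A factor-100 range around
#' 1 mg m\eqn{^{-3}} gives 0.1–10 mg m\eqn{^{-3}}.
#'
#' @param center Central concentration, mg m\eqn{^{-3}} (> 0).
#' @param ratio_range Total ratio range R (>= 1).
#' @return Named vector `c(lower, upper)`, mg m\eqn{^{-3}}.
#' @examples
#' accuracy_interval(1, 100)  # 0.1, 10
#' @export
accuracy_interval <- function(center, ratio_range) {
  stopifnot(center > 0, ratio_range >= 1)
  half <- sqrt(ratio_range)
  c(lower = center / half, upper = center * half)
}
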