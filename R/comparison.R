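#' Mean absolute error with standard error
#'
#' @param abs_errors non-negative absolute errors, days.
#' @return Named numeric vector `c(mae, se)` with
#'   `se = sd(abs_errors)/sqrt(n)`.
#' @export
mae_with_se <- function(abs_errors) {
  if (length(abs_errors) < 2L) {
    stopf("need at least 2 errors", class = "gaguard_parameter_error")
  }
  if (any(!is.finite(abs_errors)) || any(abs_errors < 0)) {
    stopf("absolute errors must be finite and non-negative",
          class = "gaguard_parameter_error")
  }
  c(mae = mean(abs_errors),
    se = stats::sd(abs_errors) / sqrt(length(abs_errors)))
}

#' Root-mean-square error with delta-method standard error
#'
#' RMSE is `sqrt(mean(e^2))`; its SE comes from the delta method on the
#' mean of squared errors: `se(rmse) = se(mean(e^2)) / (2 * rmse)`.
#'
#' @param abs_errors non-negative absolute errors, days.
#' @return Named numeric vector `c(rmse, se)`.
#' @export
rmse_with_se <- function(abs_errors) {
  if (length(abs_errors) < 2L) {
    stopf("need at least 2 errors", class = "gaguard_parameter_error")
  }
  sq <- abs_errors^2
  rmse <- sqrt(mean(sq))
  se_mean_sq <- stats::sd(sq) / sqrt(length(sq))
  c(rmse = rmse, se = if (rmse > 0) se_mean_sq / (2 * rmse) else 0)
}

#' Paired comparison of mean absolute errors
#'
#' Paired t-test on the per-scan difference of absolute errors
#' (method A minus method B), with a t-based confidence interval for the
#' MAE difference.
#'
#' @param abs_error_a,abs_error_b paired absolute errors, days.
#' @param level confidence level.
#' @return List with `difference` (mean of a - b), `ci` (lower, upper),
#'   `p_value`, `n`, and logical `degenerate` (TRUE when the differences
#'   have zero variance, in which case `ci` collapses to the point and
#'   `p_value` is `NA`).
#' @export
paired_mae_comparison <- function(abs_error_a, abs_error_b, level = 0.95) {
  if (length(abs_error_a) != length(abs_error_b)) {
    stopf("paired errors must have equal length",
          class = "gaguard_parameter_error")
  }
  n <- length(abs_error_a)
  if (n < 3L) {
    stopf("need at least 3 pairs", class = "gaguard_parameter_error")
  }
  d <- abs_error_a - abs_error_b
  if (stats::sd(d) == 0) {
    return(list(difference = mean(d), ci = c(mean(d), mean(d)),
                p_value = NA_real_, n = n, degenerate = TRUE))
  }
  tt <- stats::t.test(d, conf.level = level)
  list(difference = unname(tt$estimate), ci = as.numeric(tt$conf.int),
       p_value = tt$p.value, n = n, degenerate = FALSE)
}

#' Proportion of scans within a cutoff, paired comparison
#'
#' Computes, for two paired error columns, the proportion of scans with
#' absolute error strictly below `cutoff_days`; the difference in
#' proportions with a paired Wald 95% interval; and a McNemar test on the
#' discordant pairs (exact binomial when the discordant count is below
#' `exact_threshold`, otherwise the continuity-corrected chi-square
#' statistic `(|b - c| - 1)^2 / (b + c)`).
#'
#' @param abs_error_a,abs_error_b paired absolute errors, days.
#' @param cutoff_days strict cutoff (default 10 days).
#' @param level confidence level for the Wald interval.
#' @param exact_threshold discordant-pair count below which the exact
#'   binomial McNemar is used (default 25).
#' @return List with `proportion_a`, `proportion_b`, `difference`,
#'   `wald_ci`, `mcnemar_p`, `mcnemar_method`, discordant counts `b`
#'   (a within, b not) and `c`, and `n`.
#' @export
proportion_within <- function(abs_error_a, abs_error_b, cutoff_days = 10,
                              level = 0.95, exact_threshold = 25L) {
  if (length(abs_error_a) != length(abs_error_b)) {
    stopf("paired errors must have equal length",
          class = "gaguard_parameter_error")
  }
  n <- length(abs_error_a)
  if (n < 10L) {
    stopf("need at least 10 pairs", class = "gaguard_parameter_error")
  }
  within_a <- abs_error_a < cutoff_days
  within_b <- abs_error_b < cutoff_days
  b <- sum(within_a & !within_b)
  cc <- sum(!within_a & within_b)
  diff <- mean(within_a) - mean(within_b)
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt((b + cc) - (b - cc)^2 / n) / n
  wald_ci <- c(diff - z * se, diff + z * se)
  if (b + cc == 0L) {
    mcnemar_p <- NA_real_
    method <- "degenerate (no discordant pairs)"
  } else if (b + cc < exact_threshold) {
    mcnemar_p <- stats::binom.test(b, b + cc, 0.5)$p.value
    method <- "exact binomial"
  } else {
    stat <- (abs(b - cc) - 1)^2 / (b + cc)
    mcnemar_p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "chi-square with continuity correction"
  }
  list(proportion_a = mean(within_a), proportion_b = mean(within_b),
       difference = diff, wald_ci = wald_ci, mcnemar_p = mcnemar_p,
       mcnemar_method = method, b = b, c = cc, n = n)
}

#' Subsample one scan per participant
#'
#' For sensitivity analyses against within-participant correlation:
#' keeps exactly one uniformly chosen scan per participant.
#'
#' @param table data frame with a `participant_id` column.
#' @param seed integer seed.
#' @return The subsampled data frame (one row per participant).
#' @export
one_scan_per_participant <- function(table, seed = 1L) {
  if (is.null(table$participant_id)) {
    stopf("table must have a participant_id column",
          class = "gaguard_parameter_error")
  }
  with_seed(seed, {
    idx <- seq_len(nrow(table))
    pick <- vapply(split(idx, table$participant_id), function(i) {
      if (length(i) == 1L) i else sample(i, 1L)
    }, integer(1))
    table[sort(pick), , drop = FALSE]
  })
}

# One comparison block: MAE/RMSE pair with SEs, paired difference with CI
# and p, proportion within the cutoff.
comparison_block <- function(abs_model, abs_expert, level = 0.95,
                             cutoff_days = 10) {
  cmp <- paired_mae_comparison(abs_model, abs_expert, level)
  pw <- if (length(abs_model) >= 10L) {
    proportion_within(abs_model, abs_expert, cutoff_days, level)
  } else {
    NULL
  }
  list(
    n = length(abs_model),
    mae_model = mae_with_se(abs_model),
    mae_expert = mae_with_se(abs_expert),
    rmse_model = rmse_with_se(abs_model),
    rmse_expert = rmse_with_se(abs_expert),
    mae_difference = cmp,
    proportion_within = pw
  )
}

#' Compare model and expert GA estimation against ground truth
#'
#' Builds the paired comparison a dating-accuracy table reports: MAE and
#' RMSE of each method (with SEs), the paired MAE difference with t-based
#' CI and p-value, the proportion of scans with absolute error strictly
#' below 10 days (difference with paired Wald CI and McNemar p), and the
#' same block within each trimester.
#'
#' @param cohort a `study_cohort` with `true_ga`, `expert_ga`, `model_ga`
#'   (typically the test split).
#' @param trimester_boundary first day of the third trimester; scans with
#'   `true_ga >= boundary` form the third-trimester block (default 196).
#' @param level confidence level.
#' @param cutoff_days cutoff for the proportion-within comparison.
#' @return An object of class `comparison_report`: `overall`,
#'   `second_trimester`, `third_trimester` blocks (absent blocks are
#'   `NULL`) plus the settings used.
#' @export
comparison_report <- function(cohort, trimester_boundary = 196,
                              level = 0.95, cutoff_days = 10) {
  if (trimester_boundary <= 98 || trimester_boundary >= 280) {
    stopf("trimester_boundary must lie in (98, 280)",
          class = "gaguard_parameter_error")
  }
  abs_model <- abs(cohort$model_ga - cohort$true_ga)
  abs_expert <- abs(cohort$expert_ga - cohort$true_ga)
  second <- cohort$true_ga < trimester_boundary
  block_or_null <- function(sel) {
    if (sum(sel) < 3L) return(NULL)
    comparison_block(abs_model[sel], abs_expert[sel], level, cutoff_days)
  }
  structure(
    list(overall = comparison_block(abs_model, abs_expert, level, cutoff_days),
         second_trimester = block_or_null(second),
         third_trimester = block_or_null(!second),
         trimester_boundary = trimester_boundary,
         cutoff_days = cutoff_days, level = level),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  fmt_block <- function(b, label) {
    if (is.null(b)) {
      cat(sprintf("%s: (absent, too few scans)\n", label))
      return(invisible())
    }
    cat(sprintf("%s (n = %d):\n", label, b$n))
    cat(sprintf("  MAE  model %.2f (%.2f) vs expert %.2f (%.2f) days\n",
                b$mae_model["mae"], b$mae_model["se"],
                b$mae_expert["mae"], b$mae_expert["se"]))
    cat(sprintf("  RMSE model %.2f (%.2f) vs expert %.2f (%.2f) days\n",
                b$rmse_model["rmse"], b$rmse_model["se"],
                b$rmse_expert["rmse"], b$rmse_expert["se"]))
    d <- b$mae_difference
    cat(sprintf("  MAE difference %.2f (95%% CI %.2f, %.2f)%s\n",
                d$difference, d$ci[1], d$ci[2],
                if (is.na(d$p_value)) "" else sprintf(", p = %.3g", d$p_value)))
    if (!is.null(b$proportion_within)) {
      p <- b$proportion_within
      cat(sprintf("  |error| < %g d: %.1f%% vs %.1f%% (diff %.1f%%, CI %.1f, %.1f)\n",
                  x$cutoff_days, 100 * p$proportion_a, 100 * p$proportion_b,
                  100 * p$difference, 100 * p$wald_ci[1], 100 * p$wald_ci[2]))
    }
  }
  cat("<comparison_report> model vs expert GA estimation\n")
  fmt_block(x$overall, "Overall")
  fmt_block(x$second_trimester,
            sprintf("2nd trimester (< %g d)", x$trimester_boundary))
  fmt_block(x$third_trimester,
            sprintf("3rd trimester (>= %g d)", x$trimester_boundary))
  invisible(x)
}
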