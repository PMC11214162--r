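#' Discrepancy statistic observed by the guardrail
#'
#' At deployment the guardrail sees only the independent estimator's GA and
#' the operator's biometry-derived GA, so its flagging statistic is the
#' absolute discrepancy between the two, in days.
#'
#' @param model_ga,novice_ga GA estimates in days.
#' @return `abs(model_ga - novice_ga)`, days.
#' @export
compute_flag_statistic <- function(model_ga, novice_ga) {
  if (any(!is.finite(model_ga)) || any(!is.finite(novice_ga))) {
    stopf("GA estimates must be finite", class = "gaguard_parameter_error")
  }
  abs(model_ga - novice_ga)
}

#' Calibrate flagging thresholds at target sensitivities on a tuning set
#'
#' Walks the tuning-set ROC curve: for each target sensitivity `s`, the
#' threshold is the LARGEST candidate `t` such that the fraction of
#' gross-error scans with flag statistic `>= t` is at least `s`.
#' Candidates are restricted to the observed flag statistics of the
#' positive (gross-error) scans, giving the step-function ROC cut-points;
#' the downstream flag rule is `statistic >= t`. Thresholds are
#' non-increasing in the target sensitivity.
#'
#' @param flag_statistic numeric vector of per-scan flag statistics (days).
#' @param gross_error logical vector of gross-error labels.
#' @param target_sensitivities proportions in (0, 1\]; default
#'   `c(0.80, 0.90, 0.95)`.
#' @param min_positives minimum number of gross-error scans required for a
#'   stable calibration.
#' @return Named numeric vector of thresholds (days), one per target,
#'   names like `"80%"`.
#' @export
calibrate_thresholds <- function(flag_statistic, gross_error,
                                 target_sensitivities = c(0.80, 0.90, 0.95),
                                 min_positives = 20L) {
  keep <- !is.na(gross_error) & is.finite(flag_statistic)
  flag_statistic <- flag_statistic[keep]
  gross_error <- gross_error[keep]
  pos <- flag_statistic[gross_error]
  if (length(pos) == 0L) {
    stopf("no gross-error positives in the tuning set; cannot calibrate",
          class = "gaguard_calibration_error")
  }
  if (length(pos) < min_positives) {
    stopf("only %d gross-error positives in the tuning set (need >= %d)",
          length(pos), min_positives, class = "gaguard_calibration_error")
  }
  if (any(target_sensitivities <= 0 | target_sensitivities > 1)) {
    stopf("target sensitivities must lie in (0, 1]",
          class = "gaguard_parameter_error")
  }
  candidates <- sort(unique(pos))
  # sens(t) = P(pos >= t); over sorted candidates this is (n_pos - rank + 1)/n
  sens_at <- vapply(candidates, function(t) mean(pos >= t), numeric(1))
  thresholds <- vapply(target_sensitivities, function(s) {
    ok <- which(sens_at >= s)
    candidates[max(ok)]  # largest t still meeting the target
  }, numeric(1))
  names(thresholds) <- sprintf("%g%%", 100 * target_sensitivities)
  thresholds
}

#' Exact Clopper-Pearson confidence interval for a proportion
#'
#' The exact interval from beta-distribution quantiles:
#' lower = `qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`), upper =
#' `qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`).
#'
#' @param successes,trials counts, `0 <= successes <= trials`.
#' @param level confidence level, default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
clopper_pearson_ci <- function(successes, trials, level = 0.95) {
  if (!is_count(successes) || !is_count(trials) || trials < 1 ||
      successes > trials) {
    stopf("need 0 <= successes <= trials with trials >= 1",
          class = "gaguard_parameter_error")
  }
  if (level <= 0 || level >= 1) {
    stopf("level must lie in (0, 1)", class = "gaguard_parameter_error")
  }
  alpha <- 1 - level
  lower <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, trials - successes)
  c(lower = lower, upper = upper)
}

#' AUC with DeLong confidence interval
#'
#' Point estimate is the Mann-Whitney statistic (ties counted 1/2);
#' the variance and confidence interval use the DeLong structural
#' components as implemented in \pkg{pROC}. The interval is reported on
#' the AUC scale and clipped to \[0, 1\].
#'
#' @param statistics numeric scores (higher = more suspicious).
#' @param labels logical (or 0/1) class labels; `TRUE` = positive.
#' @param level confidence level.
#' @return Named numeric vector `c(auc, lower, upper)`.
#' @export
delong_auc_ci <- function(statistics, labels, level = 0.95) {
  labels <- as.logical(labels)
  keep <- !is.na(labels) & is.finite(statistics)
  statistics <- statistics[keep]
  labels <- labels[keep]
  if (length(unique(labels)) < 2L) {
    stopf("both classes must be present to compute an AUC",
          class = "gaguard_degenerate_error")
  }
  if (length(statistics) < 10L) {
    stopf("need at least 10 observations for DeLong inference",
          class = "gaguard_parameter_error")
  }
  roc <- pROC::roc(response = labels, predictor = statistics,
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(roc, conf.level = level, method = "delong"))
  c(auc = ci[2], lower = max(0, ci[1]), upper = min(1, ci[3]))
}

# Mann-Whitney AUC (ties 1/2) via midranks; used for the dense sensitivity
# grids where no interval is needed.
auc_mann_whitney <- function(statistics, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(labels) & is.finite(statistics)
  statistics <- statistics[keep]
  labels <- labels[keep]
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stopf("both classes must be present to compute an AUC",
          class = "gaguard_degenerate_error")
  }
  r <- rank(statistics)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate the guardrail at a calibrated threshold on a test set
#'
#' Applies the flag rule `flag_statistic >= threshold`, cross-tabulates
#' flags against gross-error labels, and reports sensitivity, specificity,
#' PPV and NPV with exact Clopper-Pearson 95% intervals, plus the AUC of
#' the flag statistic with its DeLong interval.
#'
#' @param flag_statistic numeric per-scan flag statistics (days).
#' @param gross_error logical gross-error labels.
#' @param threshold_days flagging threshold, days.
#' @param level confidence level for all intervals.
#' @return An object of class `guardrail_result`: threshold, confusion
#'   counts (`tp`, `fp`, `fn`, `tn`), a `metrics` data frame
#'   (estimate/lower/upper for sensitivity, specificity, ppv, npv), and
#'   `auc` with its interval.
#' @export
evaluate_guardrail <- function(flag_statistic, gross_error, threshold_days,
                               level = 0.95) {
  keep <- !is.na(gross_error) & is.finite(flag_statistic)
  flag_statistic <- flag_statistic[keep]
  gross_error <- as.logical(gross_error[keep])
  if (!any(gross_error) || all(gross_error)) {
    stopf("test set must contain both gross-error and clean scans",
          class = "gaguard_degenerate_error")
  }
  flagged <- flag_statistic >= threshold_days
  tp <- sum(flagged & gross_error)
  fp <- sum(flagged & !gross_error)
  fn <- sum(!flagged & gross_error)
  tn <- sum(!flagged & !gross_error)
  prop <- function(x, n) {
    if (n == 0L) {
      stopf("degenerate margin (no trials) for a guardrail metric",
            class = "gaguard_degenerate_error")
    }
    ci <- clopper_pearson_ci(x, n, level)
    c(estimate = x / n, ci)
  }
  metrics <- rbind(
    sensitivity = prop(tp, tp + fn),
    specificity = prop(tn, tn + fp),
    ppv = prop(tp, tp + fp),
    npv = prop(tn, tn + fn)
  )
  auc <- delong_auc_ci(flag_statistic, gross_error, level)
  structure(
    list(threshold_days = unname(threshold_days),
         tp = tp, fp = fp, fn = fn, tn = tn, n = tp + fp + fn + tn,
         metrics = as.data.frame(metrics), auc = auc, level = level),
    class = "guardrail_result"
  )
}

#' @export
print.guardrail_result <- function(x, digits = 3, ...) {
  cat(sprintf("<guardrail_result> threshold %.4g days, n = %d (tp %d, fp %d, fn %d, tn %d)\n",
              x$threshold_days, x$n, x$tp, x$fp, x$fn, x$tn))
  m <- round(x$metrics, digits)
  print(m)
  cat(sprintf("AUC %.3f (%d%% CI %.3f, %.3f)\n", x$auc["auc"],
              round(100 * x$level), x$auc["lower"], x$auc["upper"]))
  invisible(x)
}
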