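test_that("the flag statistic is the absolute GA discrepancy and symmetric", {
  expect_equal(compute_flag_statistic(200, 200), 0)
  expect_equal(compute_flag_statistic(200, 189.4), 10.6)
  set.seed(2)
  a <- rnorm(50, 200, 15)
  b <- rnorm(50, 200, 15)
  expect_equal(compute_flag_statistic(a, b), compute_flag_statistic(b, a))
})

test_that("threshold calibration picks the largest cut-point meeting each target", {
  pos <- 1:10
  stat <- c(pos, runif(30, 0, 0.5))
  labels <- c(rep(TRUE, 10), rep(FALSE, 30))
  thr <- calibrate_thresholds(stat, labels, c(0.8, 1.0), min_positives = 5)
  expect_equal(unname(thr["80%"]), 3)   # 8 of 10 positives >= 3
  expect_equal(unname(thr["100%"]), 1)  # capture-all: the minimum positive
  expect_error(calibrate_thresholds(runif(10), rep(FALSE, 10)),
               class = "gaguard_calibration_error")
})

test_that("calibrated thresholds meet their target tightly and order correctly", {
  set.seed(33)
  for (rep in 1:25) {
    n <- 150
    labels <- runif(n) < 0.4
    stat <- abs(rnorm(n, ifelse(labels, 8, 2), 4))
    if (sum(labels) < 20) next
    targets <- c(0.80, 0.90, 0.95)
    thr <- calibrate_thresholds(stat, labels, targets, min_positives = 20)
    pos <- stat[labels]
    cand <- sort(unique(pos))
    for (k in seq_along(targets)) {
      # brute-force oracle: enumerate every candidate cut-point
      feasible <- cand[vapply(cand, function(t) mean(pos >= t) >= targets[k],
                              logical(1))]
      expect_equal(unname(thr[k]), max(feasible))
      expect_gte(mean(pos >= thr[k]), targets[k])
      above <- cand[cand > thr[k]]
      if (length(above) > 0) {
        expect_lt(mean(pos >= min(above)), targets[k])  # tightness
      }
    }
    expect_true(all(diff(thr) <= 0))
  }
})

test_that("guardrail evaluation reproduces a hand-built confusion matrix", {
  stat <- c(rep(1, 81), rep(0, 19), rep(1, 10), rep(0, 90))
  labels <- c(rep(TRUE, 100), rep(FALSE, 100))
  res <- evaluate_guardrail(stat, labels, threshold_days = 0.5)
  expect_equal(c(res$tp, res$fn, res$fp, res$tn), c(81, 19, 10, 90))
  expect_equal(res$metrics["sensitivity", "estimate"], 0.81)
  expect_equal(res$metrics["specificity", "estimate"], 0.90)
  # Clopper-Pearson bounds against the binomial-CDF inversion oracle
  oracle <- cp_oracle(81, 100)
  expect_equal(res$metrics["sensitivity", "lower"], oracle[1],
               tolerance = 1e-4)
  expect_equal(res$metrics["sensitivity", "upper"], oracle[2],
               tolerance = 1e-4)
  expect_true(all(res$metrics$lower <= res$metrics$estimate &
                  res$metrics$estimate <= res$metrics$upper))
})

test_that("perfect separation and label-independent statistics bound the AUC", {
  stat <- c(rep(10, 40), rep(1, 60))
  labels <- c(rep(TRUE, 40), rep(FALSE, 60))
  res <- suppressWarnings(evaluate_guardrail(stat, labels, 5))
  expect_equal(res$metrics["sensitivity", "estimate"], 1)
  expect_equal(res$metrics["specificity", "estimate"], 1)
  expect_equal(unname(res$auc["auc"]), 1)

  set.seed(5)
  stat0 <- runif(4000)
  labels0 <- runif(4000) < 0.5
  null_auc <- delong_auc_ci(stat0, labels0)
  expect_true(null_auc["lower"] <= 0.5 && 0.5 <= null_auc["upper"])
  expect_equal(unname(null_auc["auc"]), 0.5, tolerance = 0.03)
})

test_that("Clopper-Pearson intervals hit exact boundaries and validate input", {
  expect_equal(clopper_pearson_ci(0, 10)[["lower"]], 0)
  expect_equal(clopper_pearson_ci(10, 10)[["upper"]], 1)
  expect_error(clopper_pearson_ci(11, 10), class = "gaguard_parameter_error")
  expect_error(clopper_pearson_ci(5, 10, level = 1.2),
               class = "gaguard_parameter_error")
})

test_that("DeLong inference handles ties, separation and degenerate input", {
  expect_equal(unname(suppressWarnings(
    delong_auc_ci(c(1, 2, rep(0, 8)),
                  c(TRUE, TRUE, rep(FALSE, 8))))["auc"]), 1)
  expect_equal(unname(delong_auc_ci(rep(3, 20),
                                    rep(c(TRUE, FALSE), 10))["auc"]), 0.5)
  expect_error(delong_auc_ci(runif(20), rep(TRUE, 20)),
               class = "gaguard_degenerate_error")
})

test_that("the AUC is invariant to strictly monotone transforms of the statistic", {
  set.seed(11)
  stat <- abs(rnorm(300, ifelse(runif(300) < 0.3, 9, 3), 3))
  labels <- runif(300) < plogis(stat - 5)
  if (length(unique(labels)) == 2) {
    a1 <- evaluate_guardrail(stat, labels, 5)$auc[["auc"]]
    a2 <- evaluate_guardrail(log1p(stat), labels, log1p(5))$auc[["auc"]]
    expect_equal(a1, a2, tolerance = 1e-12)
  }
})

test_that("sensitivity falls and specificity rises as the threshold grows", {
  set.seed(19)
  stat <- abs(rnorm(500, 5, 4))
  labels <- runif(500) < plogis(stat - 6)
  thresholds <- c(2, 5, 8, 12)
  res <- lapply(thresholds, function(t) evaluate_guardrail(stat, labels, t))
  sens <- vapply(res, function(r) r$metrics["sensitivity", "estimate"],
                 numeric(1))
  spec <- vapply(res, function(r) r$metrics["specificity", "estimate"],
                 numeric(1))
  expect_true(all(diff(sens) <= 0))
  expect_true(all(diff(spec) >= 0))
})
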