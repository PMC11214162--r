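test_that("MAE and RMSE summaries match hand arithmetic", {
  expect_equal(mae_with_se(c(3, 5)), c(mae = 4, se = 1))
  expect_equal(mae_with_se(rep(2.5, 10))[["se"]], 0)
  set.seed(6)
  x <- round(runif(10, 0, 12), 3)
  expect_equal(mae_with_se(x)[["mae"]], sum(x) / 10)
  expect_equal(mae_with_se(x)[["se"]],
               sqrt(sum((x - mean(x))^2) / 9) / sqrt(10))
  expect_equal(rmse_with_se(x)[["rmse"]], sqrt(sum(x^2) / 10))
  expect_error(mae_with_se(3), class = "gaguard_parameter_error")
})

test_that("MAE never exceeds RMSE, with equality only for constant errors", {
  set.seed(41)
  for (i in 1:20) {
    e <- abs(rnorm(50, 0, runif(1, 0.5, 6)))
    expect_lte(mae_with_se(e)[["mae"]], rmse_with_se(e)[["rmse"]])
  }
  const <- rep(3.3, 20)
  expect_equal(mae_with_se(const)[["mae"]], rmse_with_se(const)[["rmse"]])
})

test_that("paired MAE comparison handles identical, shifted and noisy columns", {
  x <- c(2, 4, 6, 3, 5)
  same <- paired_mae_comparison(x, x)
  expect_equal(same$difference, 0)
  expect_true(same$degenerate)

  shifted <- paired_mae_comparison(x, x + 1)
  expect_equal(shifted$difference, -1)
  expect_true(shifted$degenerate)
  expect_equal(diff(shifted$ci), 0)

  set.seed(10)
  a <- abs(rnorm(500, 0, 5))
  b <- abs(rnorm(500, 0, 5)) + 0.9
  cmp <- paired_mae_comparison(a, b)
  d <- a - b
  tt <- t.test(d)
  expect_equal(cmp$difference, mean(d))
  expect_equal(cmp$ci, as.numeric(tt$conf.int))
  expect_equal(cmp$p_value, tt$p.value)
})

test_that("paired-difference CI covers a simulated -0.9 day shift", {
  set.seed(17)
  hits <- 0
  for (r in 1:300) {
    a <- abs(rnorm(1000, 0, 5))
    b <- a + rnorm(1000, 0.9, 2)   # expert worse by 0.9 days on average
    ci <- paired_mae_comparison(a, b)$ci
    if (ci[1] <= -0.9 && -0.9 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits / 300, 0.93)
})

test_that("proportion-within comparison matches the hand McNemar formula", {
  # 20 discordant one way, 5 the other; 75 concordant-within pairs
  a <- c(rep(1, 95), rep(15, 5))
  b <- c(rep(1, 75), rep(15, 20), rep(1, 5))
  res <- proportion_within(a, b, cutoff_days = 10)
  expect_equal(c(res$b, res$c), c(20, 5))
  stat <- (abs(20 - 5) - 1)^2 / 25
  expect_equal(res$mcnemar_p, pchisq(stat, 1, lower.tail = FALSE))
  expect_equal(res$difference, 0.15)

  small <- proportion_within(c(rep(1, 96), rep(15, 4)),
                             c(rep(1, 92), rep(15, 4), rep(1, 4)),
                             cutoff_days = 10)
  expect_match(small$mcnemar_method, "exact")
  expect_equal(small$mcnemar_p, binom.test(4, 8, 0.5)$p.value)

  both_in <- proportion_within(rep(1, 20), rep(2, 20))
  expect_equal(both_in$difference, 0)
  expect_true(is.na(both_in$mcnemar_p))
})

test_that("the strict cutoff convention matches the empirical CDF", {
  set.seed(3)
  a <- abs(rnorm(200, 0, 6))
  b <- abs(rnorm(200, 0, 7))
  res <- proportion_within(a, b, cutoff_days = 10)
  expect_equal(res$proportion_a, ecdf(a)(10 - 1e-12))
  expect_equal(res$proportion_a, mean(a < 10))
})

test_that("trimester blocks partition on the boundary and recombine", {
  cohort <- small_cohort(500, seed = 25)
  test <- cohort[cohort$split == "test", ]
  rep_all <- comparison_report(test, trimester_boundary = 196)
  b2 <- rep_all$second_trimester
  b3 <- rep_all$third_trimester
  expect_equal(b2$n + b3$n, rep_all$overall$n)
  pooled <- (b2$n * b2$mae_model[["mae"]] + b3$n * b3$mae_model[["mae"]]) /
    rep_all$overall$n
  expect_equal(pooled, rep_all$overall$mae_model[["mae"]])

  # a scan at exactly the boundary belongs to the third trimester
  at_boundary <- test
  at_boundary$true_ga <- rep(196, nrow(test))
  rep_b <- comparison_report(at_boundary, trimester_boundary = 196)
  expect_null(rep_b$second_trimester)
  expect_equal(rep_b$third_trimester$n, nrow(test))
})

test_that("one scan per participant subsamples uniformly", {
  tbl <- data.frame(participant_id = c(1, 2, 2, 3, 3, 3), value = 1:6)
  one <- one_scan_per_participant(tbl, seed = 2)
  expect_equal(nrow(one), 3)
  expect_true(1 %in% one$value)  # single-scan participant always kept
  picks <- vapply(1:2000, function(s) {
    one_scan_per_participant(tbl, seed = s)$value[3]
  }, numeric(1))
  freq <- table(factor(picks, levels = 4:6)) / 2000
  expect_true(all(abs(freq - 1 / 3) < 0.04))
})
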