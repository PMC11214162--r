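test_that("the uniform perturbation law has the stated mean and support", {
  for (a in c(0.075, 0.10)) {
    m <- withr::with_seed(4, novice_multipliers(1e6, a))
    expect_true(all(m >= 1 - 2 * a & m <= 1 + 2 * a))
    expect_equal(mean(abs(m - 1)), a, tolerance = 0.0003 / a)
  }
  expect_error(novice_multipliers(10, 0.3), class = "gaguard_parameter_error")
})

test_that("zero perturbation is the identity and preserves the expert GA", {
  b <- invert_formula(c(140, 200, 260), ig21)
  expect_equal(perturb_biometry(b, 0), b)
  ng <- compute_novice_ga(b, ig21, shared_dating_error = c(1, -2, 0),
                          avg_abs_rel_error = 0)
  expect_true(all(ng$usable))
  expect_equal(ng$novice_ga, estimate_ga(b, ig21)$ga_days + c(1, -2, 0),
               tolerance = 1e-12)
})

test_that("inflating all measurements raises the novice GA", {
  b <- invert_formula(200, ig21)
  inflated <- as.data.frame(b)
  inflated[] <- lapply(inflated, function(v) v * 1.15)
  expect_gt(compute_novice_ga(inflated, ig21)$novice_ga,
            estimate_ga(b, ig21)$ga_days)
})

test_that("gross-error labelling uses an inclusive boundary", {
  expect_true(label_gross_error(150, 160, 10))
  expect_false(label_gross_error(150, 159.9, 10))
  expect_true(label_gross_error(150, 164, 14))
  expect_false(label_gross_error(150, 163.9, 14))
  expect_error(label_gross_error(150, 160, -1),
               class = "gaguard_parameter_error")
})

test_that("novice day-error widens with gestational age at fixed relative error", {
  ga2 <- rep(150, 3000)
  ga3 <- rep(250, 3000)
  spread <- function(ga, seed) {
    b <- invert_formula(ga, ig21)
    p <- perturb_biometry(b, 0.075, seed = seed)
    sd(estimate_ga(p, ig21)$ga_days - estimate_ga(b, ig21)$ga_days)
  }
  expect_gt(spread(ga3, 5), 1.5 * spread(ga2, 5))
})

test_that("gross-error prevalence is monotone in error level and threshold", {
  cohort <- small_cohort(400, seed = 9)
  prevalence <- function(a, thr) {
    s <- simulate_novice(cohort, ig21, avg_abs_rel_error = a,
                         gross_error_threshold = thr, seed = 17)
    mean(s$gross_error, na.rm = TRUE)
  }
  p <- vapply(c(0, 0.05, 0.075, 0.10), prevalence, numeric(1), thr = 10)
  expect_equal(p[1], 0)
  expect_true(all(diff(p) > 0))
  q <- vapply(c(7, 10, 14), prevalence, numeric(1), a = 0.075)
  expect_true(all(diff(q) < 0))
})

test_that("perturbations beyond the widened envelope are flagged unusable", {
  b <- data.frame(hc = c(250, 900), fl = c(50, 50))
  ng <- compute_novice_ga(b, ig21, avg_abs_rel_error = 0.075)
  expect_identical(ng$usable, c(TRUE, FALSE))
  expect_true(is.na(ng$novice_ga[2]))
  # in-range value perturbed to the extreme multiplier is still usable
  edge <- data.frame(hc = 400 * 1.15, fl = 50)
  expect_true(compute_novice_ga(edge, ig21, avg_abs_rel_error = 0.075)$usable)
})
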