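test_that("Intergrowth evaluation matches an independent transcription of the formula", {
  est <- estimate_ga(biometry_set(hc = 250, fl = 50), ig21)
  # direct arithmetic, written out independently of the coefficient file
  expected <- exp(3.813 + 0.03243 * log(250)^2 + 0.001644 * 50 * log(250))
  expect_equal(est$ga_days, expected, tolerance = 1e-12)
  expect_equal(est$ga_days, 191.6254, tolerance = 1e-6)
  expect_false(est$out_of_range)
})

test_that("Hadlock evaluation matches the hand-written four-parameter polynomial", {
  b <- biometry_set(bpd = 68, hc = 250, ac = 225, fl = 50)  # mm
  est <- estimate_ga(b, hadlock)
  expected_weeks <- 10.85 + 0.060 * 25.0 * 5.0 + 0.670 * 6.8 + 0.1680 * 22.5
  expect_equal(est$ga_days, expected_weeks * 7, tolerance = 1e-12)
})

test_that("estimates are strictly increasing in each measurement", {
  for (spec in list(ig21, hadlock)) {
    base <- invert_formula(c(120, 180, 240), spec)
    g0 <- estimate_ga(base, spec)$ga_days
    for (nm in spec$required_inputs) {
      bumped <- base
      bumped[[nm]] <- bumped[[nm]] * 1.02
      expect_true(all(estimate_ga(bumped, spec)$ga_days > g0),
                  info = paste(spec$name, nm))
    }
  }
})

test_that("invert/estimate round-trip is exact to 0.1 days over the GA range", {
  grid <- seq(98, 280, length.out = 50)
  for (spec in list(ig21, hadlock)) {
    b <- invert_formula(grid, spec)
    back <- estimate_ga(b, spec)$ga_days
    expect_lt(max(abs(back - grid)), 0.1)
  }
})

test_that("inversion at the range boundary stays within measurement validity", {
  b <- invert_formula(ig21$ga_valid_range[1], ig21)
  for (nm in ig21$required_inputs) {
    r <- ig21$input_valid_ranges[[nm]]
    expect_true(b[[nm]] >= r[1] && b[[nm]] <= r[2])
  }
  expect_error(invert_formula(97, ig21), class = "gaguard_range_error")
})

test_that("repeated evaluation is bit-identical", {
  b <- biometry_set(hc = c(150, 250, 330), fl = c(28, 50, 66))
  expect_identical(estimate_ga(b, ig21)$ga_days, estimate_ga(b, ig21)$ga_days)
})

test_that("formula loading validates files and round-trips through write_formula", {
  expect_setequal(ig21$required_inputs, c("hc", "fl"))

  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_formula(ig21, tmp)
  reloaded <- load_formula(tmp)
  expect_equal(reloaded, ig21)

  # deleting a coefficient must fail naming the field
  broken <- yaml::read_yaml(tmp)
  broken$coefficients$fl_loghc <- NULL
  yaml::write_yaml(broken, tmp)
  expect_error(load_formula(tmp), "required_inputs",
               class = "gaguard_load_error")

  broken2 <- yaml::read_yaml(system.file("extdata", "formulas",
                                         "intergrowth21_hcfl.yaml",
                                         package = "gaguard"))
  broken2$transform <- NULL
  yaml::write_yaml(broken2, tmp)
  expect_error(load_formula(tmp), "transform", class = "gaguard_load_error")
})

test_that("a non-monotone coefficient table is rejected at load time", {
  expect_error(
    formula_spec("bad", "linear_ga_polynomial", "mm", "days",
                 required_inputs = c("hc", "fl"),
                 coefficients = c(intercept = 200, hc = 0.2, fl = -2),
                 ga_valid_range = c(98, 294),
                 input_valid_ranges = list(hc = c(60, 400), fl = c(5, 95))),
    class = "gaguard_load_error")
})

test_that("missing and out-of-range measurements raise informative errors", {
  expect_error(estimate_ga(biometry_set(hc = 250), ig21), "fl",
               class = "gaguard_missing_measurement")
  expect_error(estimate_ga(biometry_set(hc = 250, fl = 500), ig21), "fl",
               class = "gaguard_range_error")
  expect_error(biometry_set(), class = "gaguard_missing_measurement")
  expect_error(biometry_set(hc = 100, bpd = 120))
  expect_error(biometry_set(hc = -5, fl = 20))
})

test_that("out-of-range GA estimates are flagged, never clamped", {
  est <- estimate_ga(biometry_set(hc = 395, fl = 94), ig21)
  expect_true(est$out_of_range)
  expect_gt(est$ga_days, ig21$ga_valid_range[2])
})
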