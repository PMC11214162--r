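make_config <- function(n = 400, seed = 5, em = default_em, ...) {
  experiment_config(cohort = cohort_config(n_participants = n,
                                           error_model = em),
                    master_seed = seed, ...)
}

test_that("the base case is reproducible from the master seed", {
  cfg <- make_config(300, seed = 77)
  a <- run_base_case(cfg)
  b <- run_base_case(cfg)
  expect_identical(a$thresholds, b$thresholds)
  expect_identical(a$guardrail, b$guardrail)
  expect_identical(a$scans, b$scans)
  cfg2 <- make_config(300, seed = 78)
  expect_false(identical(run_base_case(cfg2)$thresholds, a$thresholds))
})

test_that("calibrated thresholds achieve their tuning-set sensitivity", {
  res <- run_base_case(make_config(800, seed = 3))
  tune <- res$scans[res$scans$split == "tune" & res$scans$novice_usable, ]
  for (k in seq_along(res$thresholds)) {
    target <- res$config$target_sensitivities[k]
    sens <- mean(tune$flag_statistic[tune$gross_error] >= res$thresholds[k])
    expect_gte(sens, target)
  }
})

test_that("a noiseless pipeline collapses and fails gracefully at calibration", {
  cfg <- make_config(120, seed = 2, em = noiseless_em)
  expect_error(run_base_case(cfg, novice_error = 0),
               class = "gaguard_calibration_error")
  # the discrepancies really are degenerate before calibration fires
  prep <- gaguard:::prepare_experiment_cohort(cfg)
  scans <- simulate_novice(prep$cohort, cfg$cohort$formula,
                           avg_abs_rel_error = 0,
                           raw_uniforms = prep$raw_uniforms)
  expect_lt(max(abs(scans$novice_ga - scans$expert_ga)), 0.1)
  expect_lt(max(abs(scans$model_ga - scans$true_ga)), 0.1)
})

test_that("the base-case grid cell agrees with the standalone base case", {
  cfg <- make_config(500, seed = 9)
  base <- run_base_case(cfg)
  grid <- run_sensitivity_grid(cfg)
  test <- base$scans[base$scans$split == "test", ]
  base_auc <- base$guardrail[[1]]$auc[["auc"]]
  expect_equal(grid$full["+/-10 days", "7.5%"], base_auc, tolerance = 1e-12)
})

test_that("experiment configurations round-trip through YAML", {
  cfg <- make_config(500, seed = 4)
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_experiment_config(cfg, tmp)
  back <- read_experiment_config(tmp)
  expect_equal(back$master_seed, cfg$master_seed)
  expect_equal(back$cohort$error_model$expert_cv,
               cfg$cohort$error_model$expert_cv, tolerance = 1e-9)
  expect_equal(back$novice_error_levels, cfg$novice_error_levels)
  # and the round-tripped config reproduces the same analysis
  expect_identical(run_base_case(back)$thresholds,
                   run_base_case(cfg)$thresholds)
})

test_that("report rendering is idempotent and spells out missing cells", {
  cfg <- make_config(300, seed = 13)
  base <- run_base_case(cfg)
  grid <- run_sensitivity_grid(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- render_reports(base, grid, out_dir = d1)
  f2 <- render_reports(base, grid, out_dir = d2)
  for (k in seq_along(f1)) {
    expect_identical(readLines(f1[k]), readLines(f2[k]),
                     info = basename(f1[k]))
  }
  # a degenerate cell renders as NA(reason), not blank
  grid$full["+/-14 days", "10%"] <- NA
  grid$missing_reasons[["+/-14 days 10%"]] <- "no positives"
  render_reports(NULL, grid, out_dir = d1)
  tab <- read.csv(file.path(d1, "grid_full.csv"))
  bad <- tab[tab$gross_error_definition == "+/-14 days" &
               tab$novice_error_level == "10%", ]
  expect_match(bad$note, "NA\\(no positives\\)")
})
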