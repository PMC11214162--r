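#' Configure a full experiment
#'
#' Bundles the cohort configuration with the analysis grid: novice error
#' levels, gross-error definitions, target sensitivities, and the
#' model-degradation factor used to emulate a weakened independent
#' estimator. The base case (7.5% novice error, ±10-day gross error) must
#' be present in the grid.
#'
#' @param cohort a [cohort_config()].
#' @param novice_error_levels average absolute relative error levels
#'   (default `c(0.05, 0.075, 0.10)`).
#' @param gross_error_definitions gross-error thresholds in days
#'   (default `c(7, 10, 14)`).
#' @param target_sensitivities ROC calibration targets
#'   (default `c(0.80, 0.90, 0.95)`).
#' @param model_degradation_factor multiplier (>= 1) applied to the
#'   model-error mixture draw in the degraded-model grid (default 1.1).
#' @param trimester_boundary first day of the third trimester for the
#'   comparison report (default 196).
#' @param master_seed master seed; per-stage child seeds are derived from
#'   it with [with_seed()] + `sample.int` in a fixed order.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(),
                              novice_error_levels = c(0.05, 0.075, 0.10),
                              gross_error_definitions = c(7, 10, 14),
                              target_sensitivities = c(0.80, 0.90, 0.95),
                              model_degradation_factor = 1.1,
                              trimester_boundary = 196,
                              master_seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"))
  if (!any(abs(novice_error_levels - 0.075) < 1e-12) ||
      !any(gross_error_definitions == 10)) {
    stopf("the base case (7.5%% error, 10-day definition) must be in the grid",
          class = "gaguard_config_error")
  }
  if (model_degradation_factor < 1) {
    stopf("model_degradation_factor must be >= 1",
          class = "gaguard_config_error")
  }
  structure(
    list(cohort = cohort,
         novice_error_levels = sort(novice_error_levels),
         gross_error_definitions = sort(gross_error_definitions),
         target_sensitivities = sort(target_sensitivities),
         model_degradation_factor = model_degradation_factor,
         trimester_boundary = trimester_boundary,
         master_seed = as.integer(master_seed)),
    class = "experiment_config"
  )
}

# Generate + split + novice-inject a cohort for an experiment, returning
# the scan table and the raw Uniform(-1,1) draws used (for common random
# numbers across error levels).
prepare_experiment_cohort <- function(config) {
  seeds <- derive_seeds(config$master_seed)
  cc <- config$cohort
  cc$seed <- seeds[["cohort"]]
  cohort <- generate_cohort(cc)
  cohort <- split_cohort(cohort, cc$test_fraction, cc$train_tune_ratio,
                         seed = seeds[["split"]])
  raw <- with_seed(seeds[["novice"]],
                   matrix(stats::runif(4 * nrow(cohort), -1, 1), ncol = 4,
                          dimnames = list(NULL, c("bpd", "hc", "ac", "fl"))))
  list(cohort = cohort, raw_uniforms = raw, seeds = seeds)
}

#' Run the base-case analysis end to end
#'
#' Executes generate → split → novice injection (7.5% error, ±10-day gross
#' error) → threshold calibration on the tuning split → evaluation on the
#' test split, plus the model-vs-expert comparison report on the test
#' split. Fully reproducible from `master_seed`.
#'
#' @param config an [experiment_config()].
#' @param novice_error average absolute relative novice error used for the
#'   base case (default 0.075).
#' @param gross_error_threshold gross-error definition in days (default 10).
#' @return An object of class `base_case_result`: the `comparison`
#'   ([comparison_report()]), the calibrated `thresholds`, a list of
#'   [evaluate_guardrail()] results (one per target sensitivity), the
#'   stage `seeds`, and the scan table.
#' @export
run_base_case <- function(config, novice_error = 0.075,
                          gross_error_threshold = 10) {
  stopifnot(inherits(config, "experiment_config"))
  prep <- prepare_experiment_cohort(config)
  scans <- simulate_novice(prep$cohort, config$cohort$formula,
                           avg_abs_rel_error = novice_error,
                           gross_error_threshold = gross_error_threshold,
                           raw_uniforms = prep$raw_uniforms)
  scans$flag_statistic <- abs(scans$model_ga - scans$novice_ga)
  tune <- scans[scans$split == "tune", ]
  test <- scans[scans$split == "test", ]
  thresholds <- calibrate_thresholds(tune$flag_statistic, tune$gross_error,
                                     config$target_sensitivities)
  guardrail <- lapply(thresholds, function(t) {
    evaluate_guardrail(test$flag_statistic, test$gross_error, t)
  })
  comparison <- comparison_report(test, config$trimester_boundary)
  structure(
    list(comparison = comparison, thresholds = thresholds,
         guardrail = guardrail, seeds = prep$seeds, scans = scans,
         config = config),
    class = "base_case_result"
  )
}

#' @export
print.base_case_result <- function(x, ...) {
  cat("<base_case_result>\n")
  print(x$comparison)
  cat("\nCalibrated thresholds (days):\n")
  print(round(x$thresholds, 2))
  for (nm in names(x$guardrail)) {
    cat(sprintf("\nOperating point at %s tuning sensitivity:\n", nm))
    print(x$guardrail[[nm]])
  }
  invisible(x)
}

#' Run the two-way sensitivity grid
#'
#' Computes the test-split AUC of the flag statistic for every combination
#' of gross-error definition (rows) and novice error level (columns), at
#' the full model-error scale and with the model-error mixture draw
#' inflated by `model_degradation_factor`. All cells share one cohort and
#' one set of underlying Uniform(-1, 1) perturbation draws (scaled per
#' error level), so cell-to-cell differences reflect the parameters, not
#' Monte-Carlo noise.
#'
#' @param config an [experiment_config()].
#' @return An object of class `sensitivity_grid`: matrices `full` and
#'   `degraded` (rows = gross-error definitions, columns = error levels),
#'   `n_test`, and the stage `seeds`. Cells whose tuning data lack
#'   positives are `NA` with the reason recorded in `missing_reasons`.
#' @export
run_sensitivity_grid <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  prep <- prepare_experiment_cohort(config)
  cohort <- prep$cohort
  test_idx <- cohort$split == "test"
  defs <- config$gross_error_definitions
  levels <- config$novice_error_levels
  dims <- list(sprintf("+/-%g days", defs), sprintf("%g%%", 100 * levels))
  full <- matrix(NA_real_, length(defs), length(levels), dimnames = dims)
  degraded <- full
  missing_reasons <- list()
  deg_model_ga <- cohort$true_ga + cohort$shared_dating_error +
    config$model_degradation_factor * cohort$model_mixture_error
  for (j in seq_along(levels)) {
    scans <- simulate_novice(cohort, config$cohort$formula,
                             avg_abs_rel_error = levels[j],
                             gross_error_threshold = 10,  # relabelled below
                             raw_uniforms = prep$raw_uniforms)
    stat_full <- abs(scans$model_ga - scans$novice_ga)[test_idx]
    stat_deg <- abs(deg_model_ga - scans$novice_ga)[test_idx]
    delta <- scans$delta_vs_expert[test_idx]
    usable <- scans$novice_usable[test_idx]
    for (i in seq_along(defs)) {
      labels <- ifelse(usable, abs(delta) >= defs[i], NA)
      cell <- tryCatch(
        list(full = auc_mann_whitney(stat_full, labels),
             degraded = auc_mann_whitney(stat_deg, labels)),
        gaguard_degenerate_error = function(e) e
      )
      if (inherits(cell, "condition")) {
        missing_reasons[[paste(dims[[1]][i], dims[[2]][j])]] <-
          conditionMessage(cell)
      } else {
        full[i, j] <- cell$full
        degraded[i, j] <- cell$degraded
      }
    }
  }
  structure(
    list(full = full, degraded = degraded,
         degradation_factor = config$model_degradation_factor,
         n_test = sum(test_idx), seeds = prep$seeds,
         missing_reasons = missing_reasons),
    class = "sensitivity_grid"
  )
}

#' @export
print.sensitivity_grid <- function(x, digits = 3, ...) {
  cat(sprintf("<sensitivity_grid> AUC over %d test scans\n", x$n_test))
  cat("Full model error scale:\n")
  print(round(x$full, digits))
  cat(sprintf("Degraded model (error scale x %g):\n", x$degradation_factor))
  print(round(x$degraded, digits))
  if (length(x$missing_reasons) > 0) {
    cat("Missing cells:\n")
    for (nm in names(x$missing_reasons)) {
      cat("  ", nm, ": ", x$missing_reasons[[nm]], "\n", sep = "")
    }
  }
  invisible(x)
}

# --- report rendering ------------------------------------------------------

comparison_to_df <- function(report) {
  block_rows <- function(b, label) {
    if (is.null(b)) return(NULL)
    pw <- b$proportion_within
    data.frame(
      subset = label, n = b$n,
      quantity = c("MAE (days)", "RMSE (days)",
                   sprintf("Absolute error < %g days (%%)",
                           if (is.null(pw)) NA else 10)),
      model = c(b$mae_model[["mae"]], b$rmse_model[["rmse"]],
                if (is.null(pw)) NA else 100 * pw$proportion_a),
      model_se = c(b$mae_model[["se"]], b$rmse_model[["se"]], NA),
      expert = c(b$mae_expert[["mae"]], b$rmse_expert[["rmse"]],
                 if (is.null(pw)) NA else 100 * pw$proportion_b),
      expert_se = c(b$mae_expert[["se"]], b$rmse_expert[["se"]], NA),
      difference = c(b$mae_difference$difference, NA,
                     if (is.null(pw)) NA else 100 * pw$difference),
      ci_lower = c(b$mae_difference$ci[1], NA,
                   if (is.null(pw)) NA else 100 * pw$wald_ci[1]),
      ci_upper = c(b$mae_difference$ci[2], NA,
                   if (is.null(pw)) NA else 100 * pw$wald_ci[2]),
      p_value = c(b$mae_difference$p_value, NA,
                  if (is.null(pw)) NA else pw$mcnemar_p)
    )
  }
  out <- rbind(
    block_rows(report$overall, "overall"),
    block_rows(report$second_trimester, "second_trimester"),
    block_rows(report$third_trimester, "third_trimester")
  )
  out
}

guardrail_to_df <- function(guardrail, thresholds) {
  do.call(rbind, lapply(names(guardrail), function(nm) {
    g <- guardrail[[nm]]
    m <- g$metrics
    data.frame(
      tuning_sensitivity = nm,
      threshold_days = g$threshold_days,
      metric = c(rownames(m), "auc"),
      estimate = c(m$estimate, g$auc[["auc"]]),
      ci_lower = c(m$lower, g$auc[["lower"]]),
      ci_upper = c(m$upper, g$auc[["upper"]])
    )
  }))
}

grid_to_df <- function(mat, reasons) {
  df <- as.data.frame(as.table(mat), stringsAsFactors = FALSE)
  names(df) <- c("gross_error_definition", "novice_error_level", "auc")
  key <- paste(df$gross_error_definition, df$novice_error_level)
  df$note <- vapply(seq_len(nrow(df)), function(i) {
    if (!is.na(df$auc[i])) return("")
    paste0("NA(", reasons[[key[i]]] %||% "missing", ")")
  }, character(1))
  df
}

#' Render experiment results to report files
#'
#' Writes the comparison table, guardrail operating points, sensitivity
#' grids, a machine-readable JSON report, a run manifest (configuration,
#' seeds, package version) and a plain-text log into `out_dir`. Rendering
#' is deterministic: re-running on the same results produces identical
#' files. Numbers are rounded (2 decimals) only at serialization.
#'
#' @param base a `base_case_result` (or `NULL` to skip its tables).
#' @param grid a `sensitivity_grid` (or `NULL`).
#' @param out_dir output directory, created if needed.
#' @return Character vector of the files written, invisibly.
#' @export
render_reports <- function(base = NULL, grid = NULL, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("cannot create output directory '%s'", out_dir)
  }
  written <- character()
  emit_csv <- function(df, name) {
    path <- file.path(out_dir, name)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, 2)
    utils::write.csv(df, path, row.names = FALSE, na = "")
    written <<- c(written, path)
  }
  report <- list()
  manifest <- list(package = "gaguard",
                   version = as.character(utils::packageVersion("gaguard")))
  if (!is.null(base)) {
    emit_csv(comparison_to_df(base$comparison), "comparison.csv")
    emit_csv(guardrail_to_df(base$guardrail, base$thresholds),
             "guardrail.csv")
    report$thresholds_days <- as.list(round(base$thresholds, 2))
    report$guardrail <- lapply(base$guardrail, function(g) {
      list(threshold_days = round(g$threshold_days, 2),
           counts = list(tp = g$tp, fp = g$fp, fn = g$fn, tn = g$tn),
           metrics = round(g$metrics, 4), auc = round(g$auc, 4))
    })
    manifest$master_seed <- base$config$master_seed
    manifest$stage_seeds <- as.list(base$seeds)
    manifest$n_participants <- base$config$cohort$n_participants
    manifest$formula <- base$config$cohort$formula$name
    manifest$target_sensitivities <- base$config$target_sensitivities
  }
  if (!is.null(grid)) {
    emit_csv(grid_to_df(grid$full, grid$missing_reasons), "grid_full.csv")
    emit_csv(grid_to_df(grid$degraded, grid$missing_reasons),
             "grid_degraded.csv")
    report$sensitivity_grid <- list(
      full = round(grid$full, 4), degraded = round(grid$degraded, 4),
      degradation_factor = grid$degradation_factor, n_test = grid$n_test)
  }
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- c("gaguard run log",
                 sprintf("stages rendered: %s",
                         paste(c(if (!is.null(base)) "base_case",
                                 if (!is.null(grid)) "sensitivity_grid"),
                               collapse = ", ")),
                 if (!is.null(base))
                   sprintf("stage seed %s = %d", names(base$seeds),
                           base$seeds))
  writeLines(log_lines, log_path)
  invisible(c(written, report_path, manifest_path, log_path))
}

#' Read / write an experiment configuration file
#'
#' Experiment configurations round-trip through flat YAML so runs can be
#' described and reproduced outside R. Formula objects are stored by their
#' shipped name (`intergrowth21_hcfl` or `hadlock4`).
#'
#' @param config an [experiment_config()].
#' @param path YAML file path.
#' @return `write_experiment_config()` returns `path` invisibly;
#'   `read_experiment_config()` the reconstructed `experiment_config`.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  cc <- config$cohort
  em <- cc$error_model
  yaml::write_yaml(list(
    n_participants = cc$n_participants,
    formula = cc$formula$name,
    ga_distribution = cc$ga_distribution,
    visit_lambda = cc$visit_lambda, max_visits = cc$max_visits,
    test_fraction = cc$test_fraction,
    train_tune_ratio = cc$train_tune_ratio,
    error_model = list(
      model_mae_target = unname(em$targets["model_mae"]),
      model_rmse_target = unname(em$targets["model_rmse"]),
      expert_rmse_target = unname(em$targets["expert_rmse"]),
      shared_dating_sd = em$shared_dating_sd,
      expert_cv = em$expert_cv),
    novice_error_levels = config$novice_error_levels,
    gross_error_definitions = config$gross_error_definitions,
    target_sensitivities = config$target_sensitivities,
    model_degradation_factor = config$model_degradation_factor,
    trimester_boundary = config$trimester_boundary,
    master_seed = config$master_seed
  ), path, precision = 15L)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  formula <- switch(raw$formula,
                    intergrowth21_hcfl = intergrowth21_formula(),
                    hadlock4 = hadlock_formula(),
                    stopf("unknown formula '%s' in config", raw$formula,
                          class = "gaguard_config_error"))
  gd <- raw$ga_distribution
  gd$second <- as.numeric(unlist(gd$second))
  gd$third <- as.numeric(unlist(gd$third))
  em <- raw$error_model
  experiment_config(
    cohort = cohort_config(
      n_participants = raw$n_participants,
      error_model = error_model(
        model_mae_target = em$model_mae_target,
        model_rmse_target = em$model_rmse_target,
        expert_rmse_target = em$expert_rmse_target,
        shared_dating_sd = em$shared_dating_sd,
        expert_cv = em$expert_cv,
        formula = formula, ga_distribution = gd),
      formula = formula, ga_distribution = gd,
      visit_lambda = raw$visit_lambda, max_visits = raw$max_visits,
      test_fraction = raw$test_fraction,
      train_tune_ratio = raw$train_tune_ratio),
    novice_error_levels = as.numeric(unlist(raw$novice_error_levels)),
    gross_error_definitions = as.numeric(unlist(raw$gross_error_definitions)),
    target_sensitivities = as.numeric(unlist(raw$target_sensitivities)),
    model_degradation_factor = raw$model_degradation_factor,
    trimester_boundary = raw$trimester_boundary,
    master_seed = raw$master_seed
  )
}
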