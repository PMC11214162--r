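#' Calibrate a zero-mean Gaussian scale mixture to printed MAE and RMSE
#'
#' A single zero-mean Gaussian has a fixed MAE/RMSE ratio of
#' \eqn{\sqrt{2/\pi} \approx 0.798}; reported GA-error moments often imply a
#' heavier-tailed ratio. A two-component zero-mean Gaussian scale mixture
#' \eqn{w\,N(0,\sigma_1^2) + (1-w)\,N(0,\sigma_2^2)} is the minimal family
#' matching an arbitrary feasible (MAE, RMSE) pair:
#' \deqn{E|X| = \sqrt{2/\pi}\,(w\sigma_1 + (1-w)\sigma_2), \qquad
#'       E[X^2] = w\sigma_1^2 + (1-w)\sigma_2^2.}
#' The solver fixes \eqn{w = 0.8} and solves the two moment equations in
#' closed form; if the closed form leaves a negative scale it falls back to
#' a deterministic grid search over \eqn{w}.
#'
#' @param target_mae target mean absolute error, days (> 0).
#' @param target_rmse target root-mean-square error, days (>= `target_mae`).
#' @param w mixture weight of the first (narrow) component; default 0.8.
#' @return An object of class `scale_mixture`: list with `weights`, `sds`,
#'   and the achieved `mae` and `rmse` (exact, by construction).
#' @examples
#' calibrate_scale_mixture(3.87, 5.01)
#' @export
calibrate_scale_mixture <- function(target_mae, target_rmse, w = 0.8) {
  if (!is.numeric(target_mae) || target_mae <= 0 ||
      !is.numeric(target_rmse) || target_rmse <= 0) {
    stopf("target_mae and target_rmse must be positive",
          class = "gaguard_parameter_error")
  }
  cc <- sqrt(2 / pi)
  s1_bar <- target_mae / cc          # required mean of component SDs
  s2_bar <- target_rmse^2            # required mean of squared SDs
  if (s2_bar < s1_bar^2 * (1 - 1e-12)) {
    stopf(paste0("infeasible moment pair: MAE %g exceeds the Gaussian bound ",
                 "sqrt(2/pi)*RMSE = %g"), target_mae, cc * target_rmse,
          class = "gaguard_infeasible_error")
  }
  spread <- max(s2_bar - s1_bar^2, 0)
  solve_w <- function(w) {
    sig1 <- s1_bar - sqrt((1 - w) / w * spread)
    sig2 <- s1_bar + sqrt(w / (1 - w) * spread)
    if (sig1 < 0) return(NULL)
    list(weights = c(w, 1 - w), sds = c(sig1, sig2))
  }
  sol <- solve_w(w)
  if (is.null(sol)) {
    for (wg in seq(0.95, 0.05, by = -0.05)) {
      sol <- solve_w(wg)
      if (!is.null(sol)) break
    }
  }
  if (is.null(sol)) {
    stopf("no two-component mixture matches MAE %g / RMSE %g",
          target_mae, target_rmse, class = "gaguard_infeasible_error")
  }
  achieved_mae <- cc * sum(sol$weights * sol$sds)
  achieved_rmse <- sqrt(sum(sol$weights * sol$sds^2))
  if (abs(achieved_mae - target_mae) > 1e-6 * target_mae ||
      abs(achieved_rmse - target_rmse) > 1e-6 * target_rmse) {
    stopf("mixture solver failed to reproduce target moments",
          class = "gaguard_numeric_error")
  }
  structure(list(weights = sol$weights, sds = sol$sds,
                 mae = achieved_mae, rmse = achieved_rmse),
            class = "scale_mixture")
}

#' @export
print.scale_mixture <- function(x, ...) {
  cat("<scale_mixture> zero-mean Gaussian scale mixture\n")
  cat(sprintf("  components: w = %s, sd = %s days\n",
              paste(signif(x$weights, 4), collapse = "/"),
              paste(signif(x$sds, 4), collapse = "/")))
  cat(sprintf("  moments: MAE %.4f, RMSE %.4f days\n", x$mae, x$rmse))
  invisible(x)
}

#' Draw from a calibrated scale mixture
#'
#' @param n number of draws.
#' @param mixture a `scale_mixture` from [calibrate_scale_mixture()].
#' @return Numeric vector of `n` zero-mean error draws (days).
#' @export
rscale_mixture <- function(n, mixture) {
  stopifnot(inherits(mixture, "scale_mixture"))
  comp <- sample.int(length(mixture$weights), n, replace = TRUE,
                     prob = mixture$weights)
  stats::rnorm(n, 0, mixture$sds[comp])
}

#' Specify the cohort error model
#'
#' Bundles the three error components the generator uses:
#' \itemize{
#' \item `shared_dating_sd` — a per-pregnancy Gaussian error common to every
#'   GA estimate of that pregnancy, representing uncertainty in the
#'   ground-truth dating itself (which is established from one earlier
#'   scan). It induces the correlation between model and expert errors.
#' \item `model_error` — a zero-mean scale mixture for the AI estimator's
#'   independent error, calibrated to target MAE/RMSE moments.
#' \item `expert_cv` — a per-structure lognormal coefficient of variation
#'   for expert biometry measurement error. When `NULL` it is calibrated
#'   with [calibrate_expert_cv()] so the expert GA error matches
#'   `expert_rmse_target`.
#' }
#'
#' The model-error targets default to the calibration moments 3.87/5.01
#' days and the expert target to 6.47 days; the shared dating SD defaults
#' to 2.5 days. Because the moment targets include the shared component,
#' the mixture is calibrated to the residual moments after removing it.
#'
#' @param model_mae_target,model_rmse_target model GA error moments, days.
#' @param expert_rmse_target expert-biometry GA RMSE target, days.
#' @param shared_dating_sd SD of the shared dating error, days.
#' @param expert_cv optional fixed expert CV (dimensionless, <= 0.2).
#' @param formula `formula_spec` used when calibrating `expert_cv`.
#' @param ga_distribution GA distribution spec (see [cohort_config()]) used
#'   when calibrating `expert_cv`.
#' @return An object of class `error_model`.
#' @export
error_model <- function(model_mae_target = 3.87, model_rmse_target = 5.01,
                        expert_rmse_target = 6.47, shared_dating_sd = 2.5,
                        expert_cv = NULL, formula = intergrowth21_formula(),
                        ga_distribution = default_ga_distribution()) {
  if (shared_dating_sd < 0) {
    stopf("shared_dating_sd must be >= 0", class = "gaguard_parameter_error")
  }
  if (model_rmse_target > 0 && shared_dating_sd >= model_rmse_target) {
    stopf("shared_dating_sd must be below the model RMSE target",
          class = "gaguard_parameter_error")
  }
  # The printed moments describe the TOTAL error (shared + independent).
  # Adding the shared Gaussian to each mixture component just widens its SD
  # in quadrature, so: calibrate the TOTAL mixture to the targets, then
  # deflate each component SD by the shared variance. The resulting total
  # error (shared + independent mixture) then matches both targets exactly.
  if (model_rmse_target == 0 && model_mae_target == 0) {
    mix <- structure(list(weights = 1, sds = 0, mae = 0, rmse = 0),
                     class = "scale_mixture")
  } else {
    total <- calibrate_scale_mixture(model_mae_target, model_rmse_target)
    if (any(total$sds < shared_dating_sd)) {
      stopf(paste0("shared_dating_sd %g exceeds the narrow component SD %g ",
                   "of the calibrated model-error mixture"),
            shared_dating_sd, min(total$sds),
            class = "gaguard_infeasible_error")
    }
    ind_sds <- sqrt(total$sds^2 - shared_dating_sd^2)
    cc <- sqrt(2 / pi)
    mix <- structure(
      list(weights = total$weights, sds = ind_sds,
           mae = cc * sum(total$weights * ind_sds),
           rmse = sqrt(sum(total$weights * ind_sds^2))),
      class = "scale_mixture")
  }
  if (is.null(expert_cv)) {
    expert_cv <- if (expert_rmse_target == 0 && shared_dating_sd == 0) {
      0
    } else {
      calibrate_expert_cv(expert_rmse_target, formula, ga_distribution,
                          shared_dating_sd = shared_dating_sd)
    }
  }
  if (expert_cv < 0 || expert_cv > 0.2) {
    stopf("expert_cv must lie in [0, 0.2]", class = "gaguard_parameter_error")
  }
  structure(
    list(shared_dating_sd = shared_dating_sd, model_error = mix,
         expert_cv = expert_cv,
         targets = c(model_mae = model_mae_target,
                     model_rmse = model_rmse_target,
                     expert_rmse = expert_rmse_target)),
    class = "error_model"
  )
}

#' @export
print.error_model <- function(x, ...) {
  cat("<error_model>\n")
  cat(sprintf("  shared dating SD: %.3g days\n", x$shared_dating_sd))
  cat(sprintf("  expert biometry CV: %.4f\n", x$expert_cv))
  cat(sprintf("  model error mixture: MAE %.3f / RMSE %.3f days (independent part)\n",
              x$model_error$mae, x$model_error$rmse))
  invisible(x)
}

#' Calibrate the expert biometry coefficient of variation
#'
#' Per-structure relative measurement error propagates through the
#' nonlinear dating formula, so the expert CV is solved for at the GA
#' level: find the scalar CV (applied to every structure as independent
#' lognormal noise) such that the simulated RMSE of expert GA minus true
#' GA, over the cohort's GA distribution and including the shared dating
#' error, matches the target. Solved by monotone 1-D root finding on a
#' fixed-seed inner simulation; the inner draws are held fixed across CV
#' evaluations so the objective is smooth and strictly increasing.
#'
#' @param target_expert_rmse target RMSE of (expert GA - true GA), days.
#' @param formula `formula_spec` used for expert GA.
#' @param ga_distribution GA distribution spec (see
#'   [default_ga_distribution()]).
#' @param shared_dating_sd shared dating error SD, days.
#' @param n_sim inner simulation size.
#' @param inner_seed fixed seed of the inner simulation.
#' @return Scalar CV in \[0, 0.2\].
#' @export
calibrate_expert_cv <- function(target_expert_rmse,
                                formula = intergrowth21_formula(),
                                ga_distribution = default_ga_distribution(),
                                shared_dating_sd = 2.5,
                                n_sim = 4000L, inner_seed = 761543L) {
  if (target_expert_rmse < 0) {
    stopf("target RMSE must be >= 0", class = "gaguard_parameter_error")
  }
  if (target_expert_rmse == 0) {
    if (shared_dating_sd > 0) {
      stopf("target RMSE 0 is unreachable with shared_dating_sd > 0",
            class = "gaguard_infeasible_error")
    }
    return(0)
  }
  if (target_expert_rmse^2 <= shared_dating_sd^2) {
    stopf("target RMSE %g is not above the shared dating SD %g",
          target_expert_rmse, shared_dating_sd,
          class = "gaguard_infeasible_error")
  }
  draws <- with_seed(inner_seed, {
    ga <- sample_ga(n_sim, ga_distribution)
    list(ga = ga,
         eps = matrix(stats::rnorm(4 * n_sim), ncol = 4,
                      dimnames = list(NULL, c("bpd", "hc", "ac", "fl"))),
         shared = stats::rnorm(n_sim, 0, shared_dating_sd))
  })
  base <- invert_formula(draws$ga, formula)
  objective <- function(cv) {
    b <- base
    for (nm in names(b)) b[[nm]] <- b[[nm]] * exp(cv * draws$eps[, nm])
    ga_hat <- eval_formula(b[, formula$required_inputs, drop = FALSE],
                           formula) + draws$shared
    sqrt(mean((ga_hat - draws$ga)^2)) - target_expert_rmse
  }
  if (objective(0.2) < 0) {
    stopf("target RMSE %g unreachable with CV <= 0.2", target_expert_rmse,
          class = "gaguard_infeasible_error")
  }
  if (objective(0) >= 0) return(0)
  stats::uniroot(objective, c(0, 0.2), tol = 1e-6)$root
}
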