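#' Uniform novice-error multipliers
#'
#' The novice simulator replaces each measurement `m` by `m * (1 + u)` with
#' `u ~ Uniform(-2a, +2a)`, where `a` is the average absolute relative
#' error: since the mean absolute value of `Uniform(-w, w)` is `w/2`, the
#' half-width `2a` gives `E|u| = a` (so the base case `a = 0.075` draws
#' multipliers in \[0.85, 1.15\]).
#'
#' @param n number of multipliers.
#' @param avg_abs_rel_error target mean absolute relative error `a`,
#'   in \[0, 0.25\].
#' @return Numeric vector of `n` multipliers.
#' @export
novice_multipliers <- function(n, avg_abs_rel_error) {
  if (!is.numeric(avg_abs_rel_error) || length(avg_abs_rel_error) != 1L ||
      avg_abs_rel_error < 0 || avg_abs_rel_error > 0.25) {
    stopf("avg_abs_rel_error must lie in [0, 0.25]",
          class = "gaguard_parameter_error")
  }
  1 + stats::runif(n, -2 * avg_abs_rel_error, 2 * avg_abs_rel_error)
}

#' Perturb expert biometry with uniform novice error
#'
#' Applies [novice_multipliers()] independently to every present
#' measurement of every scan (independent across structures and scans).
#' With `avg_abs_rel_error = 0` the input is returned unchanged.
#'
#' @param biometry a [biometry_set()] or data frame of measurements (mm).
#' @param avg_abs_rel_error average absolute relative error `a`.
#' @param seed optional integer seed; when supplied the draw is made under
#'   [with_seed()] so the caller's RNG stream is untouched.
#' @return The perturbed measurements, same shape and class as the input.
#' @export
perturb_biometry <- function(biometry, avg_abs_rel_error, seed = NULL) {
  m <- biometry
  draw <- function() {
    if (avg_abs_rel_error > 0) {
      for (nm in intersect(c("bpd", "hc", "ac", "fl"), names(m))) {
        m[[nm]] <<- m[[nm]] * novice_multipliers(nrow(m), avg_abs_rel_error)
      }
    } else {
      # consume no RNG, but validate the parameter
      novice_multipliers(0, avg_abs_rel_error)
    }
    m
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Label a gross gestational-age error
#'
#' A novice estimate is a gross error when it differs from the expert
#' estimate by at least `threshold_days` (boundary included).
#'
#' @param novice_ga,expert_ga GA estimates in days.
#' @param threshold_days gross-error definition in days (> 0); base
#'   case 10.
#' @return Logical vector.
#' @examples
#' label_gross_error(150, 160, 10)   # TRUE: boundary included
#' label_gross_error(150, 159.9, 10) # FALSE
#' @export
label_gross_error <- function(novice_ga, expert_ga, threshold_days = 10) {
  if (!is.numeric(threshold_days) || threshold_days <= 0) {
    stopf("threshold_days must be positive", class = "gaguard_parameter_error")
  }
  if (any(!is.finite(novice_ga)) || any(!is.finite(expert_ga))) {
    stopf("GA estimates must be finite", class = "gaguard_parameter_error")
  }
  abs(novice_ga - expert_ga) >= threshold_days
}

#' Compute the novice GA estimate for perturbed biometry
#'
#' The novice GA is the dating formula applied to the perturbed biometry
#' plus the SAME shared dating error as the parent pregnancy (novice and
#' expert read the same ground-truth reference). Perturbation can push a
#' measurement outside the formula's validity envelope; the envelope is
#' first widened by the perturbation half-width `2a` so that legitimate
#' perturbations of in-range values are never rejected, and scans still
#' outside are flagged unusable (GA set to `NA`) rather than evaluated.
#'
#' @param novice_biometry perturbed measurements (mm).
#' @param spec `formula_spec`.
#' @param shared_dating_error per-scan shared dating error, days.
#' @param avg_abs_rel_error the `a` used for the perturbation (sets the
#'   envelope widening).
#' @return List with `novice_ga` (days, `NA` where unusable) and logical
#'   `usable`.
#' @export
compute_novice_ga <- function(novice_biometry, spec, shared_dating_error = 0,
                              avg_abs_rel_error = 0.075) {
  m <- as_biometry_df(novice_biometry)[, spec$required_inputs, drop = FALSE]
  usable <- rep_len(TRUE, nrow(m))
  for (nm in spec$required_inputs) {
    r <- spec$input_valid_ranges[[nm]]
    lo <- r[1] * (1 - 2 * avg_abs_rel_error)
    hi <- r[2] * (1 + 2 * avg_abs_rel_error)
    usable <- usable & m[[nm]] >= lo & m[[nm]] <= hi
  }
  ga <- rep_len(NA_real_, nrow(m))
  if (any(usable)) {
    ga[usable] <- eval_formula(m[usable, , drop = FALSE], spec) +
      rep_len(shared_dating_error, nrow(m))[usable]
  }
  list(novice_ga = ga, usable = usable)
}

#' Simulate novice biometry for a whole cohort
#'
#' Runs the novice-error injection end to end on a generated cohort:
#' perturb the expert biometry ([perturb_biometry()]), recompute GA
#' ([compute_novice_ga()]), and label gross errors
#' ([label_gross_error()]).
#'
#' @param cohort a `study_cohort` (see [generate_cohort()]), with or
#'   without split labels.
#' @param spec `formula_spec` used for the novice GA.
#' @param avg_abs_rel_error average absolute relative perturbation `a`
#'   (base case 0.075).
#' @param gross_error_threshold gross-error definition, days (base
#'   case 10).
#' @param seed integer seed for the perturbation draws.
#' @param raw_uniforms optional matrix (`nrow(cohort)` x 4, columns
#'   bpd/hc/ac/fl) of Uniform(-1, 1) draws; when given they are scaled by
#'   `2a` instead of fresh draws, enabling common random numbers across
#'   error levels in sensitivity analyses.
#' @return The cohort with appended columns `novice_bpd`, `novice_hc`,
#'   `novice_ac`, `novice_fl`, `novice_ga`, `novice_usable`,
#'   `delta_vs_expert` and `gross_error`.
#' @export
simulate_novice <- function(cohort, spec, avg_abs_rel_error = 0.075,
                            gross_error_threshold = 10, seed = 1L,
                            raw_uniforms = NULL) {
  stopifnot(inherits(spec, "formula_spec"))
  n <- nrow(cohort)
  structures <- c("bpd", "hc", "ac", "fl")
  if (is.null(raw_uniforms)) {
    raw_uniforms <- with_seed(seed, matrix(stats::runif(4 * n, -1, 1),
                                           ncol = 4,
                                           dimnames = list(NULL, structures)))
  }
  novice <- as.data.frame(cohort)[, structures]
  for (nm in structures) {
    novice[[nm]] <- novice[[nm]] *
      (1 + 2 * avg_abs_rel_error * raw_uniforms[, nm])
  }
  ng <- compute_novice_ga(novice, spec, cohort$shared_dating_error,
                          avg_abs_rel_error)
  cohort$novice_bpd <- novice$bpd
  cohort$novice_hc <- novice$hc
  cohort$novice_ac <- novice$ac
  cohort$novice_fl <- novice$fl
  cohort$novice_ga <- ng$novice_ga
  cohort$novice_usable <- ng$usable
  cohort$delta_vs_expert <- ng$novice_ga - cohort$expert_ga
  cohort$gross_error <- ifelse(
    ng$usable,
    abs(cohort$delta_vs_expert) >= gross_error_threshold,
    NA
  )
  cohort
}
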