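#' @name ga_formulas
#' @title Coefficient-table-driven gestational-age dating formulas
#'
#' @description
#' Published dating formulas estimate gestational age (GA) from fetal
#' biometry via low-order polynomials, either on the GA scale directly
#' (`linear_ga_polynomial`, e.g. the Hadlock multi-parameter formula) or on
#' the log-GA scale (`log_ga_polynomial`, e.g. the Intergrowth-21st
#' HC/FL formula). A formula is described entirely by a coefficient file:
#' its required measurements, native measurement unit, output GA unit,
#' named term coefficients, and validity ranges. `load_formula()` reads and
#' validates such a file; `estimate_ga()` evaluates it; `invert_formula()`
#' numerically constructs "median fetus" biometry consistent with a target
#' GA, which the cohort generator uses.
#'
#' GA is handled in days everywhere inside the package.
NULL

# Term dictionary: each supported coefficient name maps to a function of the
# measurement columns (already converted to the formula's native unit).
.formula_terms <- list(
  intercept = function(m) rep_len(1, nrow(m)),
  bpd       = function(m) m$bpd,
  hc        = function(m) m$hc,
  ac        = function(m) m$ac,
  fl        = function(m) m$fl,
  loghc     = function(m) log(m$hc),
  loghc2    = function(m) log(m$hc)^2,
  fl_loghc  = function(m) m$fl * log(m$hc),
  hc_fl     = function(m) m$hc * m$fl,
  bpd2      = function(m) m$bpd^2,
  ac2       = function(m) m$ac^2,
  fl2       = function(m) m$fl^2
)

.term_inputs <- list(
  intercept = character(), bpd = "bpd", hc = "hc", ac = "ac", fl = "fl",
  loghc = "hc", loghc2 = "hc", fl_loghc = c("fl", "hc"), hc_fl = c("hc", "fl"),
  bpd2 = "bpd", ac2 = "ac", fl2 = "fl"
)

#' Load a dating-formula specification from a coefficient file
#'
#' Coefficient files are flat YAML: `name`, `transform`
#' (`log_ga_polynomial` or `linear_ga_polynomial`), `native_unit`
#' (`mm` or `cm`), `ga_unit` (`days` or `weeks`), `required_inputs`,
#' named `coefficients`, `ga_valid_range` (days) and per-measurement
#' `input_valid_ranges` (mm). Monotonicity of the estimator in each
#' required measurement is checked numerically at load time.
#'
#' @param coefficient_file path to a YAML coefficient file.
#' @return A validated object of class `formula_spec`.
#' @seealso [intergrowth21_formula()], [hadlock_formula()] for the shipped
#'   formulas.
#' @export
load_formula <- function(coefficient_file) {
  if (!file.exists(coefficient_file)) {
    stopf("coefficient file not found: %s", coefficient_file,
          class = "gaguard_load_error")
  }
  raw <- tryCatch(yaml::read_yaml(coefficient_file), error = function(e) {
    stopf("malformed coefficient file '%s': %s", coefficient_file,
          conditionMessage(e), class = "gaguard_load_error")
  })
  required_fields <- c("name", "transform", "native_unit", "ga_unit",
                       "required_inputs", "coefficients",
                       "ga_valid_range", "input_valid_ranges")
  missing <- setdiff(required_fields, names(raw))
  if (length(missing) > 0L) {
    stopf("coefficient file '%s' is missing field(s): %s", coefficient_file,
          paste(missing, collapse = ", "), class = "gaguard_load_error")
  }
  spec <- formula_spec(
    name = raw$name,
    transform = raw$transform,
    native_unit = raw$native_unit,
    ga_unit = raw$ga_unit,
    required_inputs = unlist(raw$required_inputs),
    coefficients = unlist(raw$coefficients),
    ga_valid_range = as.numeric(unlist(raw$ga_valid_range)),
    input_valid_ranges = lapply(raw$input_valid_ranges, as.numeric)
  )
  spec
}

#' Construct and validate a dating-formula specification
#'
#' Usually reached through [load_formula()]; exposed so that formulas can be
#' built programmatically (e.g. in tests).
#'
#' @param name formula identifier.
#' @param transform `"log_ga_polynomial"` (the polynomial gives log GA) or
#'   `"linear_ga_polynomial"` (the polynomial gives GA directly).
#' @param native_unit unit the coefficients expect, `"mm"` or `"cm"`;
#'   measurements are always supplied to the package in mm and converted.
#' @param ga_unit unit of the polynomial's output, `"days"` or `"weeks"`.
#' @param required_inputs subset of `c("bpd","hc","ac","fl")`.
#' @param coefficients named numeric vector over the supported term
#'   dictionary (`intercept`, `bpd`, `hc`, `ac`, `fl`, `loghc`, `loghc2`,
#'   `fl_loghc`, `hc_fl`, `bpd2`, `ac2`, `fl2`).
#' @param ga_valid_range length-2 numeric, days, within \[98, 300\].
#' @param input_valid_ranges named list of length-2 numeric ranges in mm,
#'   one per required input.
#' @return An object of class `formula_spec`.
#' @export
formula_spec <- function(name, transform, native_unit, ga_unit,
                         required_inputs, coefficients,
                         ga_valid_range, input_valid_ranges) {
  if (!transform %in% c("log_ga_polynomial", "linear_ga_polynomial")) {
    stopf("unknown transform '%s'", transform, class = "gaguard_load_error")
  }
  if (!native_unit %in% c("mm", "cm")) {
    stopf("native_unit must be 'mm' or 'cm'", class = "gaguard_load_error")
  }
  if (!ga_unit %in% c("days", "weeks")) {
    stopf("ga_unit must be 'days' or 'weeks'", class = "gaguard_load_error")
  }
  required_inputs <- as.character(required_inputs)
  if (length(required_inputs) == 0L ||
      !all(required_inputs %in% c("bpd", "hc", "ac", "fl"))) {
    stopf("required_inputs must be a non-empty subset of bpd, hc, ac, fl",
          class = "gaguard_load_error")
  }
  coefficients <- unlist(coefficients)
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients)))) {
    stopf("coefficients must be named", class = "gaguard_load_error")
  }
  unknown <- setdiff(names(coefficients), names(.formula_terms))
  if (length(unknown) > 0L) {
    stopf("unknown coefficient term(s): %s", paste(unknown, collapse = ", "),
          class = "gaguard_load_error")
  }
  used <- unique(unlist(.term_inputs[names(coefficients)]))
  if (!setequal(used, required_inputs)) {
    stopf("coefficients use inputs {%s} but required_inputs declares {%s}",
          paste(sort(used), collapse = ","),
          paste(sort(required_inputs), collapse = ","),
          class = "gaguard_load_error")
  }
  if (length(ga_valid_range) != 2L || ga_valid_range[1] >= ga_valid_range[2] ||
      ga_valid_range[1] < 98 || ga_valid_range[2] > 300) {
    stopf("ga_valid_range must be increasing and within [98, 300] days",
          class = "gaguard_load_error")
  }
  missing_rng <- setdiff(required_inputs, names(input_valid_ranges))
  if (length(missing_rng) > 0L) {
    stopf("input_valid_ranges missing for: %s",
          paste(missing_rng, collapse = ", "), class = "gaguard_load_error")
  }
  for (nm in required_inputs) {
    r <- input_valid_ranges[[nm]]
    if (length(r) != 2L || r[1] <= 0 || r[1] >= r[2]) {
      stopf("input_valid_ranges$%s must be a positive increasing pair", nm,
            class = "gaguard_load_error")
    }
  }
  spec <- structure(
    list(name = name, transform = transform, native_unit = native_unit,
         ga_unit = ga_unit, required_inputs = required_inputs,
         coefficients = coefficients, ga_valid_range = ga_valid_range,
         input_valid_ranges = input_valid_ranges[required_inputs]),
    class = "formula_spec"
  )
  check_monotonicity(spec)
  spec
}

# Numeric monotonicity check: along the median trajectory, nudge each
# required input upward and require the GA estimate to strictly increase.
check_monotonicity <- function(spec, n_grid = 25L) {
  s <- seq(spec$ga_valid_range[1], spec$ga_valid_range[2], length.out = n_grid)
  base <- median_biometry(s)[, spec$required_inputs, drop = FALSE]
  g0 <- eval_formula(base, spec)
  for (nm in spec$required_inputs) {
    bumped <- base
    bumped[[nm]] <- bumped[[nm]] * 1.01
    g1 <- eval_formula(bumped, spec)
    if (!all(g1 > g0)) {
      stopf("formula '%s' is not strictly increasing in '%s'",
            spec$name, nm, class = "gaguard_load_error")
    }
  }
  invisible(spec)
}

#' Write a formula specification back to a coefficient file
#'
#' Inverse of [load_formula()]: `load_formula(write_formula(spec, f))`
#' returns an equal specification.
#'
#' @param spec a `formula_spec`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_formula <- function(spec, path) {
  stopifnot(inherits(spec, "formula_spec"))
  yaml::write_yaml(
    list(name = spec$name, transform = spec$transform,
         native_unit = spec$native_unit, ga_unit = spec$ga_unit,
         required_inputs = as.list(spec$required_inputs),
         coefficients = as.list(spec$coefficients),
         ga_valid_range = spec$ga_valid_range,
         input_valid_ranges = spec$input_valid_ranges),
    path, precision = 15L
  )
  invisible(path)
}

#' @export
print.formula_spec <- function(x, ...) {
  cat("<formula_spec> ", x$name, "\n",
      "  transform: ", x$transform, " (", x$native_unit, " -> GA ",
      x$ga_unit, ")\n",
      "  inputs: ", paste(x$required_inputs, collapse = ", "), "\n",
      "  GA valid range: [", x$ga_valid_range[1], ", ", x$ga_valid_range[2],
      "] days\n", sep = "")
  invisible(x)
}

#' Shipped dating formulas
#'
#' `intergrowth21_formula()` is the Intergrowth-21st GA estimation formula
#' from head circumference and femur length (log-GA polynomial, mm, days).
#' `hadlock_formula()` is the Hadlock four-parameter formula from BPD, HC,
#' AC and FL (linear GA polynomial, cm, weeks). Both are loaded from the
#' versioned coefficient files shipped under `inst/extdata/formulas`.
#'
#' @return A `formula_spec`.
#' @export
intergrowth21_formula <- function() {
  load_formula(system.file("extdata", "formulas", "intergrowth21_hcfl.yaml",
                           package = "gaguard", mustWork = TRUE))
}

#' @rdname intergrowth21_formula
#' @export
hadlock_formula <- function() {
  load_formula(system.file("extdata", "formulas", "hadlock4.yaml",
                           package = "gaguard", mustWork = TRUE))
}

# Raw polynomial evaluation: measurements in mm, returns GA in days.
# No range validation here; estimate_ga() is the validating wrapper.
eval_formula <- function(measurements, spec) {
  m <- as.data.frame(measurements)
  if (spec$native_unit == "cm") m[] <- lapply(m, function(v) v / 10)
  acc <- 0
  for (nm in names(spec$coefficients)) {
    acc <- acc + spec$coefficients[[nm]] * .formula_terms[[nm]](m)
  }
  ga <- if (spec$transform == "log_ga_polynomial") exp(acc) else acc
  if (spec$ga_unit == "weeks") ga <- ga * 7
  ga
}

#' Estimate gestational age from fetal biometry
#'
#' Evaluates a dating formula on one or more scans. Inputs are validated
#' against the formula's required measurements and validity ranges;
#' estimates falling outside the formula's GA validity range are flagged
#' (never clamped).
#'
#' @param biometry a [biometry_set()] (or data frame with measurement
#'   columns in mm).
#' @param spec a `formula_spec`, e.g. [intergrowth21_formula()].
#' @return An object of class `ga_estimate`: list with `ga_days` (numeric
#'   vector), `formula_name`, and logical `out_of_range` flags.
#' @examples
#' estimate_ga(biometry_set(hc = 250, fl = 50), intergrowth21_formula())
#' @export
estimate_ga <- function(biometry, spec) {
  stopifnot(inherits(spec, "formula_spec"))
  m <- as_biometry_df(biometry)
  missing <- setdiff(spec$required_inputs, names(m))
  if (length(missing) > 0L) {
    stopf("formula '%s' requires measurement(s) not present: %s",
          spec$name, paste(missing, collapse = ", "),
          class = "gaguard_missing_measurement")
  }
  m <- m[, spec$required_inputs, drop = FALSE]
  if (any(!vapply(m, is.numeric, logical(1))) ||
      any(!is.finite(as.matrix(m)))) {
    stopf("measurements must be finite numerics",
          class = "gaguard_range_error")
  }
  for (nm in spec$required_inputs) {
    r <- spec$input_valid_ranges[[nm]]
    bad <- m[[nm]] < r[1] | m[[nm]] > r[2]
    if (any(bad)) {
      stopf("measurement '%s' outside valid range [%g, %g] mm (e.g. %g)",
            nm, r[1], r[2], m[[nm]][which(bad)[1]],
            class = "gaguard_range_error")
    }
  }
  ga <- eval_formula(m, spec)
  structure(
    list(ga_days = ga, formula_name = spec$name,
         out_of_range = ga < spec$ga_valid_range[1] |
           ga > spec$ga_valid_range[2]),
    class = "ga_estimate"
  )
}

#' @export
print.ga_estimate <- function(x, ...) {
  cat("<ga_estimate> formula:", x$formula_name, "\n")
  print(data.frame(ga_days = x$ga_days, out_of_range = x$out_of_range), ...)
  invisible(x)
}

# Reference median fetal biometry trajectory (mm), weeks 12-46, from
# standard growth-chart medians. This is the latent growth curve the
# generator walks along: one scalar "median-trajectory age" determines all
# four measurements jointly.
.median_growth_table <- data.frame(
  week = seq(12, 46, by = 2),
  bpd  = c(19, 27, 35, 41, 47, 53, 60, 66, 71, 76, 81, 85, 88, 91, 94, 96, 98, 100),
  hc   = c(70, 98, 124, 151, 175, 198, 221, 242, 262, 280, 296, 310, 322, 332, 340, 345, 350, 355),
  ac   = c(56, 81, 105, 129, 152, 175, 197, 219, 240, 260, 282, 302, 322, 342, 360, 372, 381, 389),
  fl   = c(8, 14.5, 20.5, 26.5, 32, 37.5, 43, 47.5, 52, 56.5, 61, 64.5, 68, 71, 74, 76, 78, 80)
)

.median_splines <- local({
  d <- .median_growth_table
  x <- d$week * 7
  lapply(d[c("bpd", "hc", "ac", "fl")], function(y) {
    stats::splinefun(x, y, method = "hyman")
  })
})

#' Median fetal biometry along the reference growth trajectory
#'
#' Returns the "median fetus" measurements at a given trajectory age, using
#' monotone Hermite interpolation of reference growth-chart medians
#' (weeks 12–46). All four measurements are driven by the single scalar
#' age, so the returned biometry is internally consistent.
#'
#' @param trajectory_days numeric vector of trajectory ages in days,
#'   within \[84, 322\].
#' @return Data frame with columns `bpd`, `hc`, `ac`, `fl` in mm.
#' @export
median_biometry <- function(trajectory_days) {
  if (any(trajectory_days < 84) || any(trajectory_days > 322)) {
    stopf("trajectory age must lie within [84, 322] days",
          class = "gaguard_range_error")
  }
  as.data.frame(lapply(.median_splines, function(f) f(trajectory_days)))
}

#' Invert a dating formula along the median growth trajectory
#'
#' Constructs biometry consistent with a target gestational age: the fetus
#' is parameterized by a single latent age along the reference median
#' trajectory ([median_biometry()]), and a bisection root-finder solves for
#' the latent age at which the formula's estimate equals the target. The
#' round-trip `estimate_ga(invert_formula(ga))` agrees with `ga` to better
#' than 0.1 days (bisection is run to ~1e-4 days).
#'
#' @param ga_days numeric vector of target GAs in days; each must lie in
#'   the formula's `ga_valid_range`.
#' @param spec a `formula_spec`.
#' @return A data frame of class `biometry_set` with columns `bpd`, `hc`,
#'   `ac`, `fl` (all four trajectory measurements, of which the formula
#'   uses its required subset).
#' @export
invert_formula <- function(ga_days, spec) {
  stopifnot(inherits(spec, "formula_spec"))
  if (any(!is.finite(ga_days))) {
    stopf("ga_days must be finite", class = "gaguard_range_error")
  }
  rng <- spec$ga_valid_range
  if (any(ga_days < rng[1]) || any(ga_days > rng[2])) {
    stopf("target GA outside formula valid range [%g, %g] days",
          rng[1], rng[2], class = "gaguard_range_error")
  }
  g <- function(s) eval_formula(median_biometry(s)[, spec$required_inputs,
                                                   drop = FALSE], spec)
  lo <- rep_len(84, length(ga_days))
  hi <- rep_len(322, length(ga_days))
  f_lo <- g(lo) - ga_days
  f_hi <- g(hi) - ga_days
  if (any(f_lo > 0) || any(f_hi < 0)) {
    stopf(paste0("median-trajectory bracket does not contain target GA ",
                 "(formula '%s'; bracket estimates [%0.1f, %0.1f] days)"),
          spec$name, g(84), g(322), class = "gaguard_numeric_error")
  }
  # vectorized bisection; 45 halvings of a 238-day bracket -> < 1e-8 days
  for (i in seq_len(45L)) {
    mid <- (lo + hi) / 2
    f_mid <- g(mid) - ga_days
    below <- f_mid < 0
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  b <- median_biometry((lo + hi) / 2)
  structure(b, class = c("biometry_set", "data.frame"))
}
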