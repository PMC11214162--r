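#' Default gestational-age distribution of the synthetic cohort
#'
#' A two-component uniform mixture over the second and third trimesters,
#' approximating late presentation to antenatal care: 55% of scans uniform
#' on \[98, 195\] days and 45% uniform on \[196, 280\] days.
#'
#' @param p_second proportion of scans in the second-trimester block.
#' @param second,third length-2 GA ranges (days) for the two blocks.
#' @return A GA-distribution spec (list) consumed by [cohort_config()].
#' @export
default_ga_distribution <- function(p_second = 0.55,
                                    second = c(98, 195),
                                    third = c(196, 280)) {
  if (p_second < 0 || p_second > 1) {
    stopf("p_second must lie in [0, 1]", class = "gaguard_config_error")
  }
  list(type = "two_uniform_mixture", p_second = p_second,
       second = second, third = third)
}

# Draw n true GAs from a GA-distribution spec (caller controls the seed).
sample_ga <- function(n, dist) {
  if (!identical(dist$type, "two_uniform_mixture")) {
    stopf("unknown ga_distribution type '%s'", dist$type,
          class = "gaguard_config_error")
  }
  early <- stats::runif(n) < dist$p_second
  ifelse(early,
         stats::runif(n, dist$second[1], dist$second[2]),
         stats::runif(n, dist$third[1], dist$third[2]))
}

#' Configure a synthetic cohort
#'
#' @param n_participants number of participants (>= 10 for splitting).
#' @param error_model an [error_model()]; defaults to the standard
#'   calibration (model MAE/RMSE 3.87/5.01 days, expert RMSE 6.47 days,
#'   shared dating SD 2.5 days).
#' @param formula `formula_spec` used for the expert biometry GA estimate
#'   (default Intergrowth-21st).
#' @param ga_distribution GA distribution spec, see
#'   [default_ga_distribution()].
#' @param visit_lambda mean of the Poisson part of the per-participant
#'   visit count (visits = 1 + Poisson(`visit_lambda`), truncated at
#'   `max_visits`).
#' @param max_visits maximum visits per participant.
#' @param test_fraction participant fraction assigned to the test split.
#' @param train_tune_ratio ratio of training to tuning participants among
#'   the non-test remainder.
#' @param seed integer seed controlling cohort generation.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 5000L,
                          error_model = gaguard::error_model(),
                          formula = intergrowth21_formula(),
                          ga_distribution = default_ga_distribution(),
                          visit_lambda = 0.5, max_visits = 8L,
                          test_fraction = 0.20, train_tune_ratio = 4,
                          seed = 1L) {
  if (!is_count(n_participants) || n_participants < 1) {
    stopf("n_participants must be a positive count",
          class = "gaguard_config_error")
  }
  if (test_fraction <= 0 || test_fraction >= 1) {
    stopf("test_fraction must lie in (0, 1)", class = "gaguard_config_error")
  }
  if (train_tune_ratio <= 0) {
    stopf("train_tune_ratio must be positive", class = "gaguard_config_error")
  }
  stopifnot(inherits(error_model, "error_model"),
            inherits(formula, "formula_spec"))
  structure(
    list(n_participants = as.integer(n_participants),
         error_model = error_model, formula = formula,
         ga_distribution = ga_distribution,
         visit_lambda = visit_lambda, max_visits = as.integer(max_visits),
         test_fraction = test_fraction, train_tune_ratio = train_tune_ratio,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> ", x$n_participants, " participants, formula: ",
      x$formula$name, ", seed ", x$seed, "\n", sep = "")
  print(x$error_model)
  invisible(x)
}

#' Generate a synthetic ultrasound cohort
#'
#' Simulates participants, visits and per-scan GA estimates with the error
#' structure of [error_model()]:
#' \itemize{
#' \item true GA drawn from the configured GA distribution, one draw per
#'   visit;
#' \item expert biometry: the median-trajectory biometry at the true GA
#'   ([invert_formula()]), each structure multiplied by independent
#'   lognormal noise `exp(N(0, cv))`;
#' \item expert GA: the dating formula applied to expert biometry plus the
#'   pregnancy's shared dating error;
#' \item model GA: true GA plus the shared dating error plus an independent
#'   scale-mixture draw.
#' }
#' The shared dating error (one Gaussian draw per pregnancy) makes all
#' estimates of one pregnancy err together, emulating uncertainty in the
#' ground-truth dating. The raw error components are kept as columns so
#' downstream sensitivity analyses can rescale them under common random
#' numbers.
#'
#' @param config a [cohort_config()].
#' @return A data frame of class `study_cohort`, one row per scan, with
#'   columns `participant_id`, `visit_index`, `true_ga`, the expert
#'   biometry (`bpd`, `hc`, `ac`, `fl` in mm), `expert_ga`, `model_ga`,
#'   `shared_dating_error`, `model_mixture_error`, and `split`
#'   (`NA` until [split_cohort()] is applied).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  em <- config$error_model
  with_seed(config$seed, {
    n_p <- config$n_participants
    visits <- pmin(1L + stats::rpois(n_p, config$visit_lambda),
                   config$max_visits)
    pid <- rep.int(seq_len(n_p), visits)
    n <- length(pid)
    true_ga <- sample_ga(n, config$ga_distribution)
    shared <- rep.int(stats::rnorm(n_p, 0, em$shared_dating_sd), visits)
    base_biometry <- invert_formula(true_ga, config$formula)
    expert_biometry <- base_biometry
    if (em$expert_cv > 0) {
      for (nm in names(expert_biometry)) {
        expert_biometry[[nm]] <- expert_biometry[[nm]] *
          exp(stats::rnorm(n, 0, em$expert_cv))
      }
    }
    expert_est <- estimate_ga(expert_biometry, config$formula)
    mix_err <- if (all(em$model_error$sds == 0)) {
      numeric(n)
    } else {
      rscale_mixture(n, em$model_error)
    }
    visit_index <- sequence(visits)
    cohort <- data.frame(
      participant_id = pid,
      visit_index = visit_index,
      true_ga = true_ga,
      bpd = expert_biometry$bpd, hc = expert_biometry$hc,
      ac = expert_biometry$ac, fl = expert_biometry$fl,
      expert_ga = expert_est$ga_days + shared,
      model_ga = true_ga + shared + mix_err,
      shared_dating_error = shared,
      model_mixture_error = mix_err,
      split = NA_character_
    )
    structure(cohort, class = c("study_cohort", "data.frame"),
              formula_name = config$formula$name)
  })
}

#' Assign train/tune/test splits at the participant level
#'
#' Participants (never individual scans) are randomized: first
#' `round(test_fraction * n)` participants form the test split, then the
#' remainder is divided so that the tuning split holds
#' `max(1, round(remainder / (ratio + 1)))` participants and the training
#' split the rest — a 4:1 train:tune division at the default ratio.
#'
#' @param cohort a `study_cohort` data frame.
#' @param test_fraction participant fraction for the test split.
#' @param train_tune_ratio train:tune participant ratio for the remainder.
#' @param seed integer seed for the participant randomization.
#' @return The cohort with its `split` column filled with
#'   `"train"`/`"tune"`/`"test"`.
#' @export
split_cohort <- function(cohort, test_fraction = 0.20, train_tune_ratio = 4,
                         seed = 1L) {
  ids <- unique(cohort$participant_id)
  n <- length(ids)
  if (n < 10L) {
    stopf("at least 10 participants are required to split (got %d)", n,
          class = "gaguard_split_error")
  }
  n_test <- round(test_fraction * n)
  remainder <- n - n_test
  n_tune <- max(1L, round(remainder / (train_tune_ratio + 1)))
  n_train <- remainder - n_tune
  if (n_test < 1L || n_train < 1L) {
    stopf("split sizes degenerate for n = %d participants", n,
          class = "gaguard_split_error")
  }
  shuffled <- with_seed(seed, sample(ids))
  label <- rep(c("test", "tune", "train"), times = c(n_test, n_tune, n_train))
  names(label) <- as.character(shuffled)
  cohort$split <- unname(label[as.character(cohort$participant_id)])
  cohort
}

#' Write / read a cohort scan table
#'
#' The cohort is stored as a flat comma-separated table, one row per scan,
#' for inspection and reuse outside R.
#'
#' @param cohort a `study_cohort` data frame.
#' @param path CSV file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns the `study_cohort` data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(cohort, class = c("study_cohort", "data.frame"))
}
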