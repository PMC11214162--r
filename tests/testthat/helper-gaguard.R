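# Shared fixtures: built once per test run, in code.

ig21 <- intergrowth21_formula()
hadlock <- hadlock_formula()

# Calibrating the expert CV simulates through the formula; do it once.
default_em <- error_model()

noiseless_em <- error_model(model_mae_target = 0, model_rmse_target = 0,
                            expert_rmse_target = 0, shared_dating_sd = 0)

small_cohort <- function(n_participants = 400, seed = 7,
                         em = default_em, split_seed = 11) {
  cfg <- cohort_config(n_participants = n_participants, error_model = em,
                       seed = seed)
  split_cohort(generate_cohort(cfg), seed = split_seed)
}

# Independent draw from the default GA distribution (55% U(98,195), 45%
# U(196,280)), written out rather than routed through the package.
sample_ga_for_test <- function(n) {
  early <- runif(n) < 0.55
  ifelse(early, runif(n, 98, 195), runif(n, 196, 280))
}

# Brute-force Clopper-Pearson oracle: invert the binomial CDF over a p-grid.
cp_oracle <- function(k, n, level = 0.95, step = 1e-5) {
  alpha <- 1 - level
  p <- seq(0, 1, by = step)
  lower <- if (k == 0) 0 else {
    min(p[pbinom(k - 1, n, p, lower.tail = FALSE) >= alpha / 2])
  }
  upper <- if (k == n) 1 else max(p[pbinom(k, n, p) >= alpha / 2])
  c(lower, upper)
}

# Independent Mann-Whitney AUC oracle (pairwise comparisons, ties 1/2);
# deliberately brute-force and separate from the package's rank-based path.
oracle_auc <- function(stat, labels) {
  pos <- stat[labels]
  neg <- stat[!labels]
  cmp <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  mean(cmp)
}
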