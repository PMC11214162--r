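# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Derive named per-stage child seeds from one master seed; the mapping is a
# fixed draw order so a stage's stream never depends on which stages run.
derive_seeds <- function(master_seed) {
  stages <- c("cohort", "split", "novice", "subsample", "grid", "extra")
  s <- with_seed(master_seed, sample.int(.Machine$integer.max - 1L, length(stages)))
  names(s) <- stages
  s
}

stopf <- function(fmt, ..., class = NULL) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "gaguard_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
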