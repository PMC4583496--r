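# Shared fixtures: a small mixed-kind schema, random cohort builders, and
# the exhaustive pair-enumeration concordance oracle.

tiny_schema <- function() {
  cohort_schema(
    variable_spec("age", "continuous", units = "years"),
    variable_spec("bmi", "continuous", units = "kg/m2"),
    variable_spec("fh", "binary"),
    variable_spec("smoking", "categorical",
                  categories = c("current", "past", "no")),
    variable_spec("y", "binary")
  )
}

# Random cohort on the tiny schema with independent MCAR holes outside y.
random_tiny_table <- function(n = 50, miss_rate = 0.1, seed = 1,
                              miss_outcome = FALSE) {
  withr::with_seed(seed, {
    df <- data.frame(
      age = rnorm(n, 50, 10),
      bmi = rnorm(n, 28, 5),
      fh = rbinom(n, 1, 0.3),
      smoking = sample(c("current", "past", "no"), n, replace = TRUE),
      y = rbinom(n, 1, 0.25)
    )
    vars <- c("age", "bmi", "fh", "smoking", if (miss_outcome) "y")
    for (v in vars) df[[v]][runif(n) < miss_rate] <- NA
    cohort_table(df, tiny_schema(), "y")
  })
}

# O(n^2) concordance by brute-force pair enumeration, ties counting 0.5.
brute_force_c <- function(predictions, outcomes) {
  p1 <- predictions[outcomes == 1]
  p0 <- predictions[outcomes == 0]
  cmp <- outer(p1, p0, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Two-variable cohort with a known logistic outcome, used for recovery
# and MAR experiments: y ~ expit(b0 + b1 x1 + b2 x2).
known_model_config <- function(n, b0 = -1, b1 = 0.5, b2 = 0.3) {
  truth <- risk_model_spec("truth", b0, list(
    model_term("x1", b1), model_term("x2", b2)))
  generator_config(
    n = n,
    continuous = list(x1 = c(0, 1, -6, 6), x2 = c(0, 1, -6, 6)),
    outcome_name = "y", outcome_model = truth,
    correlation = list(list("x1", "x2", 0.3))
  )
}

# Character cell matrix without format() padding, for cell-wise comparisons.
cell_matrix <- function(df) {
  m <- vapply(df, as.character, character(nrow(df)))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(df))
  m
}
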