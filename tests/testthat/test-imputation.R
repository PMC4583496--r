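test_that("complete-case deletion keeps exactly the fully observed rows", {
  tab <- random_tiny_table(n = 5, miss_rate = 0, seed = 1)
  tab$data$bmi[2] <- NA
  tab$data$smoking[4] <- NA
  cc <- complete_case(tab)
  expect_equal(n_participants(cc$table), 3)
  expect_identical(cc$method, "deletion")
  expect_identical(cc$table$data, tab$data[c(1, 3, 5), ],
                   ignore_attr = TRUE)
  # complete table -> identity
  full <- random_tiny_table(n = 8, miss_rate = 0, seed = 2)
  expect_identical(complete_case(full)$table$data, full$data)
  # zero complete rows -> degenerate-output warning in the log
  allmiss <- random_tiny_table(n = 3, miss_rate = 0, seed = 3)
  allmiss$data$bmi <- NA_real_
  expect_match(complete_case(allmiss)$log, "zero complete rows")
})

test_that("deletion n matches the MCAR independence product over seeds", {
  cfg <- bellville_default_config(n = 1083)
  rates <- vapply(cfg$missingness, `[[`, numeric(1), "rate")
  expected <- 1083 * prod(1 - rates)
  reps <- 40
  ns <- numeric(reps)
  for (i in seq_len(reps)) {
    co <- generate_complete_cohort(cfg$generator, seed = 400 + i)
    am <- apply_missingness(co, cfg$missingness, seed = 500 + i)
    ns[i] <- n_participants(complete_case(am)$table)
  }
  se <- sd(ns) / sqrt(reps)
  expect_lt(abs(mean(ns) - expected), 3 * se)
})

test_that("simple imputation fills means and observed modes", {
  tab <- random_tiny_table(n = 4, miss_rate = 0, seed = 4)
  tab$data$age <- c(1, 2, 3, NA)
  si <- simple_impute(tab)
  expect_equal(si$table$data$age[4], 2.0)
  expect_equal(mean(si$table$data$age), mean(c(1, 2, 3)))  # mean preserved
  expect_false(anyNA(si$table$data))
  expect_true(all(si$imputed_mask == missing_mask(tab)))
})

test_that("simple imputation preserves means and never inflates the SD", {
  for (seed in 1:5) {
    tab <- random_tiny_table(n = 60, miss_rate = 0.2, seed = seed)
    si <- simple_impute(tab)
    for (v in c("age", "bmi")) {
      expect_equal(mean(si$table$data[[v]]),
                   mean(tab$data[[v]], na.rm = TRUE))
      expect_lte(sd(si$table$data[[v]]), sd(tab$data[[v]], na.rm = TRUE))
    }
    # observed cells untouched
    obs <- !missing_mask(tab)
    expect_identical(cell_matrix(si$table$data)[obs],
                     cell_matrix(tab$data)[obs])
  }
  allmiss <- random_tiny_table(n = 3, miss_rate = 0, seed = 1)
  allmiss$data$bmi <- NA_real_
  expect_error(simple_impute(allmiss), "bmi")
})

test_that("conditional mean imputation recovers exact linear relations", {
  schema <- cohort_schema(variable_spec("x", "continuous"),
                          variable_spec("z", "continuous"),
                          variable_spec("y", "binary"))
  df <- data.frame(x = c(1, 2, 3, 4, 5, 6, 5),
                   z = c(2, 4, 6, 8, 10, 12, NA),
                   y = c(0, 1, 0, 1, 0, 1, 0))
  tab <- cohort_table(df, schema, "y")
  ci <- conditional_mean_impute(tab)
  expect_equal(ci$table$data$z[7], 10.0, tolerance = 1e-8)  # z = 2x
  expect_identical(ci$method, "conditional")
})

test_that("conditional imputation leaves doubly-incomplete rows missing", {
  schema <- cohort_schema(variable_spec("x", "continuous"),
                          variable_spec("z", "continuous"),
                          variable_spec("y", "binary"))
  df <- data.frame(x = c(1:8, NA), z = c(2 * (1:8), NA),
                   y = rep(c(0, 1, 0), 3))
  tab <- cohort_table(df, schema, "y")
  ci <- conditional_mean_impute(tab)
  expect_true(is.na(ci$table$data$z[9]))   # predictor x also missing
  expect_true(is.na(ci$table$data$x[9]))
  expect_false(ci$imputed_mask[9, "z"])
})

test_that("conditional fills beat unconditional fills on linear data", {
  cfg <- known_model_config(800)
  co <- generate_complete_cohort(cfg, seed = 61)
  truth <- co$data$x1
  mc <- missingness_config(x1 = list(mechanism = "MCAR", rate = 0.2))
  am <- apply_missingness(co, mc, seed = 62)
  holes <- is.na(am$data$x1)
  cond <- conditional_mean_impute(am)$table$data$x1[holes]
  simp <- simple_impute(am)$table$data$x1[holes]
  expect_lt(mean(abs(cond - truth[holes])),
            mean(abs(simp - truth[holes])))
})

test_that("stochastic imputation reduces to conditional fills at zero noise", {
  schema <- cohort_schema(variable_spec("x", "continuous"),
                          variable_spec("z", "continuous"),
                          variable_spec("y", "binary"))
  df <- data.frame(x = c(1, 2, 3, 4, 5, 6, 5),
                   z = c(2, 4, 6, 8, 10, 12, NA),
                   y = c(0, 1, 0, 1, 0, 1, 0))
  tab <- cohort_table(df, schema, "y")
  st <- stochastic_regression_impute(tab, seed = 1)
  expect_equal(st$table$data$z[7],
               conditional_mean_impute(tab)$table$data$z[7],
               tolerance = 1e-6)
})

test_that("stochastic fill noise matches the residual variance", {
  cfg <- known_model_config(400)
  co <- generate_complete_cohort(cfg, seed = 71)
  am <- co
  am$data$x1[1] <- NA       # a single hole, predictors complete
  # residual variance of the conditional fit on complete rows
  fit <- lm(x1 ~ x2 + y, data = co$data[-1, ])
  sigma2 <- sum(residuals(fit)^2) / fit$df.residual
  draws <- vapply(1:500, function(s)
    stochastic_regression_impute(am, seed = s)$table$data$x1[1], numeric(1))
  mc_se <- sigma2 * sqrt(2 / 499)  # SE of a variance estimate from 500 draws
  expect_lt(abs(var(draws) - sigma2), 3 * mc_se)
  expect_false(anyNA(
    stochastic_regression_impute(am, seed = 1)$table$data))
})

test_that("stochastic binary fills follow the fitted class probability", {
  # hand-built table where the logistic fit for fh is the empirical rate
  schema <- cohort_schema(variable_spec("x", "continuous"),
                          variable_spec("fh", "binary"),
                          variable_spec("y", "binary"))
  set.seed(81)
  n <- 300
  df <- data.frame(x = rnorm(n), fh = rbinom(n, 1, 0.3),
                   y = rbinom(n, 1, 0.5))
  df$fh[1] <- NA
  tab <- cohort_table(df, schema, "y")
  draws <- vapply(1:1000, function(s)
    stochastic_regression_impute(tab, seed = s)$table$data$fh[1],
    integer(1))
  p <- mean(df$fh, na.rm = TRUE)
  expect_lt(abs(mean(draws) - p), 3 * sqrt(p * (1 - p) / 1000) + 0.05)
})

test_that("stochastic imputation completes rows missing predictors too", {
  tab <- random_tiny_table(n = 120, miss_rate = 0.25, seed = 91,
                           miss_outcome = TRUE)
  st <- stochastic_regression_impute(tab, seed = 92)
  expect_false(anyNA(st$table$data))
  obs <- !missing_mask(tab)
  expect_identical(cell_matrix(st$table$data)[obs], cell_matrix(tab$data)[obs])
  # reproducible under the same seed
  st2 <- stochastic_regression_impute(tab, seed = 92)
  expect_identical(st$table$data, st2$table$data)
})

test_that("chained-equations MI meets its structural contract", {
  tab <- random_tiny_table(n = 100, miss_rate = 0.2, seed = 93,
                           miss_outcome = TRUE)
  mi <- mice_impute(tab, m = 3, iterations = 3, seed = 94)
  expect_equal(mi$m, 3)
  expect_length(mi$datasets, 3)
  mask <- missing_mask(tab)
  for (d in mi$datasets) {
    expect_false(anyNA(d$table$data))
    expect_true(all(d$imputed_mask == mask))
    expect_identical(cell_matrix(d$table$data)[!mask],
                     cell_matrix(tab$data)[!mask])
  }
  # different chains differ on the imputed cells
  expect_false(identical(mi$datasets[[1]]$table$data,
                         mi$datasets[[2]]$table$data))
  # bit-identical reproduction under identical arguments
  mi2 <- mice_impute(tab, m = 3, iterations = 3, seed = 94)
  expect_identical(lapply(mi$datasets, function(d) d$table$data),
                   lapply(mi2$datasets, function(d) d$table$data))
  expect_error(mice_impute(tab, m = 1, seed = 1), "m >= 2")
})

test_that("MI on a complete table returns m identical copies", {
  tab <- random_tiny_table(n = 40, miss_rate = 0, seed = 95)
  mi <- mice_impute(tab, m = 4, iterations = 2, seed = 96)
  for (d in mi$datasets) expect_identical(d$table$data, tab$data)
})

test_that("MI results serialise to per-dataset CSVs plus a manifest", {
  tab <- random_tiny_table(n = 30, miss_rate = 0.15, seed = 97)
  mi <- mice_impute(tab, m = 2, iterations = 2, seed = 98)
  dir <- withr::local_tempdir()
  paths <- write_mi_result(mi, dir)
  expect_length(list.files(dir, pattern = "imputed_.*csv"), 2)
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(man$m, 2)
  expect_equal(man$seed, 98)
  back <- read_cohort(file.path(dir, "imputed_01.csv"), tiny_schema(), "y")
  expect_equal(back$data, mi$datasets[[1]]$table$data)
})

test_that("Rubin pooling reproduces the closed form and its invariants", {
  p <- rubin_pool(c(0.5, 0.7), c(0.04, 0.04))
  expect_equal(p$q_bar, 0.6)
  expect_equal(p$w, 0.04)
  expect_equal(p$b, 0.02)
  expect_equal(p$t, 0.07)
  expect_equal(p$df, (2 - 1) * (1 + 0.04 / ((1 + 1 / 2) * 0.02))^2)
  # degenerate b
  p0 <- rubin_pool(rep(0.6, 4), c(0.01, 0.02, 0.03, 0.04))
  expect_equal(p0$b, 0)
  expect_equal(p0$t, p0$w)
  expect_identical(p0$df, Inf)
  expect_error(rubin_pool(0.5, 0.1), "m >= 2")
  expect_error(rubin_pool(c(0.5, 0.6), c(0.1, -0.1)), ">= 0")
})

test_that("pooled totals dominate within-variance on random inputs", {
  withr::with_seed(99, {
    for (i in 1:50) {
      m <- sample(2:10, 1)
      est <- rnorm(m)
      v <- runif(m, 0, 0.5)
      p <- rubin_pool(est, v)
      expect_gte(p$t, p$w)
      expect_gte(p$q_bar, min(est))
      expect_lte(p$q_bar, max(est))
      # q_bar invariant under permutation
      o <- sample(m)
      expect_equal(rubin_pool(est[o], v[o])$q_bar, p$q_bar)
    }
  })
})

test_that("no imputation method ever modifies an observed cell", {
  tab <- random_tiny_table(n = 80, miss_rate = 0.2, seed = 100,
                           miss_outcome = TRUE)
  obs <- !missing_mask(tab)
  ref <- cell_matrix(tab$data)[obs]
  for (method in c("simple", "conditional", "stochastic")) {
    out <- impute_method(tab, method, seed = 5)
    expect_identical(cell_matrix(out$table$data)[obs], ref, label = method)
  }
  mi <- impute_method(tab, "mice", m = 2, iterations = 2, seed = 5)
  for (d in mi$datasets)
    expect_identical(cell_matrix(d$table$data)[obs], ref)
})
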