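test_that("model spec validation rejects malformed transforms", {
  expect_error(model_term("age", 1, "band", breaks = c(3, 2),
                          scores = c(0, 1, 2)), "strictly increasing")
  expect_error(model_term("age", 1, "band", breaks = c(1, 2),
                          scores = c(0, 1)), "scores")
  expect_error(model_term("age", 1, "wavelet"), "arg")
  expect_error(risk_model_spec("m", NA), "intercept|number")
  # intercept-only model is valid
  m0 <- risk_model_spec("null", 0)
  expect_length(m0$terms, 0)
})

test_that("model specs round-trip through YAML", {
  m <- risk_model_spec("demo", -2.5, list(
    model_term("age", 0.05),
    model_term("smoking", 0.7, "indicator", category = "current"),
    model_term("bmi", 1, "band", breaks = c(25, 30),
               scores = c(0, 0.4, 0.9)),
    model_term(transform = "product", coefficient = 0.2, components = list(
      model_term("age"), model_term("fh")))
  ))
  path <- withr::local_tempfile(fileext = ".yaml")
  save_model_spec(m, path)
  back <- load_model_spec(path)
  expect_equal(back, m)
})

test_that("prediction follows the logistic closed form", {
  tab <- random_tiny_table(n = 5, miss_rate = 0, seed = 6)
  m0 <- risk_model_spec("null", 0)
  expect_equal(predict_risk(m0, tab)$probability, rep(0.5, 5))
  # single identity term: expit(ln 3) = 0.75
  tab$data$age <- rep(log(3), 5)
  m1 <- risk_model_spec("one", 0, list(model_term("age", 1)))
  expect_equal(predict_risk(m1, tab)$probability, rep(0.75, 5))
  # the predict() S3 method is the same engine
  expect_equal(predict(m1, tab)$probability, rep(0.75, 5))
})

test_that("transforms evaluate indicators, bands and products", {
  tab <- random_tiny_table(n = 3, miss_rate = 0, seed = 7)
  tab$data$smoking <- c("current", "past", "no")
  tab$data$bmi <- c(22, 27, 31)
  tab$data$fh <- c(1L, 1L, 0L)
  m <- risk_model_spec("t", 0, list(
    model_term("smoking", 2, "indicator", category = "current"),
    model_term("bmi", 1, "band", breaks = c(25, 30),
               scores = c(0, 0.5, 1)),
    model_term(transform = "product", coefficient = 3, components = list(
      model_term("fh"),
      model_term("smoking", 1, "indicator", category = "past")))
  ))
  lp <- linear_predictor(m, tab$data)
  expect_equal(lp, c(2 + 0, 0.5 + 3, 1))
})

test_that("rows missing a required predictor are unscorable, not scored", {
  tab <- random_tiny_table(n = 6, miss_rate = 0, seed = 8)
  tab$data$bmi[2] <- NA
  m <- risk_model_spec("m", 0, list(model_term("age", 0.01),
                                    model_term("bmi", 0.1)))
  pr <- predict_risk(m, tab)
  expect_equal(pr$n_scored, 5)
  expect_equal(pr$n_unscorable, 1)
  expect_true(is.na(pr$probability[2]))
  expect_equal(pr$n_scored + pr$n_unscorable, 6)
  expect_error(predict_risk(
    risk_model_spec("bad", 0, list(model_term("nope"))), tab),
    "absent variable")
})

test_that("predictions are monotone in positively weighted predictors", {
  tab <- random_tiny_table(n = 50, miss_rate = 0, seed = 9)
  m <- risk_model_spec("m", -1, list(model_term("age", 0.05),
                                     model_term("fh", 0.6)))
  p1 <- predict_risk(m, tab)$probability
  tab2 <- tab
  tab2$data$age <- tab2$data$age + 5
  p2 <- predict_risk(m, tab2)$probability
  expect_true(all(p2 >= p1))
})

test_that("expit is symmetric and clamps extreme linear predictors", {
  lp <- c(-50, -3, 0, 3, 50)
  expect_equal(expit(lp) + expit(-lp), rep(1, 5))
  expect_true(all(expit(lp) > 0 & expit(lp) < 1))
})

test_that("row permutation permutes predictions identically", {
  tab <- random_tiny_table(n = 30, miss_rate = 0, seed = 10)
  m <- risk_model_spec("m", -1, list(model_term("age", 0.05)))
  p <- predict_risk(m, tab)$probability
  o <- sample(30)
  tab2 <- tab
  tab2$data <- tab$data[o, ]
  expect_equal(predict_risk(m, tab2)$probability, p[o])
})

test_that("intercept recalibration drives E/O to one without moving C", {
  cfg <- known_model_config(2000)
  co <- generate_complete_cohort(cfg, seed = 55)
  biased <- risk_model_spec("biased", -1 + 0.8, list(
    model_term("x1", 0.5), model_term("x2", 0.3)))
  rec <- recalibrate_intercept(biased, co)
  y <- co$data$y
  pr <- predict_risk(rec, co)$probability
  expect_lt(abs(sum(pr) / sum(y) - 1), 1e-6)
  # discrimination untouched: shift is rank-preserving
  c0 <- c_statistic(predict_risk(biased, co)$probability, y)$c
  expect_equal(c_statistic(pr, y)$c, c0, tolerance = 1e-12)
  # already calibrated model: delta ~ 0
  rec2 <- recalibrate_intercept(rec, co)
  expect_lt(abs(attr(rec2, "delta")), 1e-3)
})

test_that("recalibration recovers a known intercept shift", {
  # the recovered shift is noisy through the realised event count, so
  # average it over independent cohorts of n = 5000
  cfg <- known_model_config(5000)
  shifted <- risk_model_spec("shifted", -1 - 0.7, list(
    model_term("x1", 0.5), model_term("x2", 0.3)))
  deltas <- vapply(1:5, function(i) {
    co <- generate_complete_cohort(cfg, seed = 560 + i)
    attr(recalibrate_intercept(shifted, co), "delta")
  }, numeric(1))
  expect_lt(abs(mean(deltas) - 0.7), 0.05)
})

test_that("recalibration rejects single-class outcomes", {
  tab <- random_tiny_table(n = 10, miss_rate = 0, seed = 57)
  tab$data$y <- 0L
  m <- risk_model_spec("m", 0, list(model_term("age", 0.01)))
  expect_error(recalibrate_intercept(m, tab), "event")
})

test_that("built-in registry ships five age-bearing validated models", {
  reg <- builtin_registry()
  expect_length(reg, 5)
  expect_setequal(names(reg), c("cambridge", "kuwaiti", "omani",
                                "rotterdam", "finnish_simplified"))
  for (m in reg) {
    expect_s3_class(m, "risk_model_spec")
    expect_true("age" %in% model_variables(m))
    # each shipped file validates through the loader used above
  }
  expect_error(builtin_registry(withr::local_tempdir()), "missing model spec")
})
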