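#' Configure the synthetic cohort generator
#'
#' Describes a complete (fully observed) cohort: truncated-normal continuous
#' variables, Bernoulli binary variables, categorical variables with fixed
#' probability vectors, and a binary outcome drawn from a known logistic
#' model — so that downstream imputation and validation stages can be tested
#' against a known truth. Continuous variables may be coupled through a
#' Gaussian copula with a user-supplied pairwise correlation.
#'
#' @param n participant count.
#' @param continuous named list; each element `c(mean, sd, lower, upper)`
#'   (physiologic truncation bounds).
#' @param binary named numeric vector of prevalences in \[0, 1\].
#' @param categorical named list; each element a named probability vector
#'   over the category labels (sums to 1).
#' @param outcome_name name of the generated binary outcome.
#' @param outcome_model `risk_model_spec` used as the data-generating truth:
#'   the outcome is Bernoulli(expit(linear predictor)).
#' @param correlation list of `list(var1, var2, rho)` entries for pairs of
#'   continuous variables (the implied correlation matrix must be positive
#'   definite).
#' @param var_order optional character vector fixing schema column order.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n, continuous = list(), binary = numeric(),
                             categorical = list(),
                             outcome_name = "undiagnosed_diabetes",
                             outcome_model = NULL, correlation = list(),
                             var_order = NULL) {
  stopifnot(n >= 0)
  for (nm in names(continuous)) {
    p <- continuous[[nm]]
    if (length(p) < 2 || p[2] <= 0)
      stop("continuous spec '", nm, "' needs (mean, sd>0)", call. = FALSE)
  }
  if (length(binary) && (any(binary < 0) || any(binary > 1)))
    stop("binary prevalences must lie in [0, 1]", call. = FALSE)
  for (nm in names(categorical)) {
    p <- categorical[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("categorical probabilities for '", nm, "' must sum to 1",
           call. = FALSE)
  }
  structure(
    list(n = as.integer(n), continuous = continuous, binary = binary,
         categorical = categorical, outcome_name = outcome_name,
         outcome_model = outcome_model, correlation = correlation,
         var_order = var_order),
    class = "generator_config"
  )
}

generator_schema <- function(config) {
  specs <- list()
  for (nm in names(config$continuous))
    specs[[nm]] <- variable_spec(nm, "continuous")
  for (nm in names(config$binary))
    specs[[nm]] <- variable_spec(nm, "binary")
  for (nm in names(config$categorical))
    specs[[nm]] <- variable_spec(nm, "categorical",
                                 categories = names(config$categorical[[nm]]))
  specs[[config$outcome_name]] <- variable_spec(config$outcome_name, "binary")
  ord <- config$var_order %||% names(specs)
  cohort_schema(specs[ord])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Correlation matrix over the continuous variables from the pair list.
build_corr_matrix <- function(config) {
  nms <- names(config$continuous)
  R <- diag(length(nms))
  dimnames(R) <- list(nms, nms)
  for (pr in config$correlation) {
    v1 <- pr[[1]]; v2 <- pr[[2]]; rho <- as.numeric(pr[[3]])
    if (!all(c(v1, v2) %in% nms))
      stop("correlation names unknown continuous variable", call. = FALSE)
    R[v1, v2] <- rho; R[v2, v1] <- rho
  }
  R
}

# Inverse CDF of a truncated normal: u in (0,1) -> value in [lower, upper].
qtruncnorm <- function(u, mean, sd, lower, upper) {
  pa <- stats::pnorm(lower, mean, sd)
  pb <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pa + u * (pb - pa), mean, sd)
}

#' Generate a complete synthetic cohort
#'
#' Draws a fully observed cohort table from a [generator_config()]:
#' continuous variables from truncated normals (coupled by a Gaussian copula
#' when a correlation is configured), binary variables Bernoulli,
#' categorical variables from their probability vectors, and the outcome
#' Bernoulli(expit(lp)) under the configured outcome model. Identical seeds
#' give bit-identical cohorts.
#'
#' @param config a `generator_config`.
#' @param seed integer seed (NULL = use the current RNG stream).
#' @return a fully observed `cohort_table`.
#' @export
generate_complete_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(seed, {
    n <- config$n
    cols <- list()
    cn <- names(config$continuous)
    if (length(cn)) {
      R <- build_corr_matrix(config)
      L <- tryCatch(chol(R), error = function(e)
        stop("correlation structure is not positive definite", call. = FALSE))
      z <- matrix(stats::rnorm(n * length(cn)), nrow = n,
                  ncol = length(cn)) %*% L
      u <- stats::pnorm(z)
      dim(u) <- dim(z)   # pnorm drops dims on zero-row input
      for (j in seq_along(cn)) {
        p <- config$continuous[[cn[j]]]
        lower <- if (length(p) >= 3) p[3] else -Inf
        upper <- if (length(p) >= 4) p[4] else Inf
        cols[[cn[j]]] <- qtruncnorm(u[, j], p[1], p[2], lower, upper)
      }
    }
    for (nm in names(config$binary))
      cols[[nm]] <- stats::rbinom(n, 1, config$binary[[nm]])
    for (nm in names(config$categorical)) {
      pr <- config$categorical[[nm]]
      cols[[nm]] <- if (n > 0)
        sample(names(pr), n, replace = TRUE, prob = pr) else character(0)
    }
    df <- if (n > 0) as.data.frame(cols, check.names = FALSE) else {
      d <- as.data.frame(lapply(cols, function(x) x[0]), check.names = FALSE)
      d
    }
    if (is.null(config$outcome_model)) {
      df[[config$outcome_name]] <- rep(0L, n)
    } else {
      lp <- linear_predictor(config$outcome_model, df)
      df[[config$outcome_name]] <- stats::rbinom(n, 1, expit(lp))
    }
    cohort_table(df, generator_schema(config), config$outcome_name)
  })
}

#' Configure an amputation pass
#'
#' Per-variable missingness mechanisms for deliberately introducing missing
#' values into a complete table:
#'
#' * `MCAR` — each cell missing independently with probability `rate`;
#' * `MAR` — missing with probability `expit(a + dependence %*% drivers)`,
#'   drivers standardised, with the intercept `a` calibrated so the marginal
#'   missingness rate equals `rate`;
#' * `MNAR` — as MAR with the variable's own (pre-amputation) value as the
#'   single driver.
#'
#' @param ... named per-variable entries, each
#'   `list(mechanism = "MCAR"|"MAR"|"MNAR", rate = <fraction>,
#'   dependence = <named weight vector over driver variables>)`
#'   (`dependence` required for MAR, self-weight scalar for MNAR).
#' @return object of class `missingness_config`.
#' @export
missingness_config <- function(...) {
  entries <- list(...)
  if (length(entries) == 1 && is.null(names(entries)) &&
      !is.null(names(entries[[1]])))
    entries <- entries[[1]]
  amputed <- names(entries)
  for (nm in amputed) {
    e <- entries[[nm]]
    e$mechanism <- match.arg(e$mechanism %||% "MCAR",
                             c("MCAR", "MAR", "MNAR"))
    if (is.null(e$rate) || e$rate < 0 || e$rate >= 1)
      stop("rate for '", nm, "' must lie in [0, 1)", call. = FALSE)
    if (e$mechanism == "MAR") {
      if (is.null(e$dependence) || is.null(names(e$dependence)))
        stop("MAR entry '", nm, "' needs a named dependence vector",
             call. = FALSE)
      bad <- intersect(names(e$dependence), amputed)
      if (length(bad))
        stop("MAR driver(s) ", paste(bad, collapse = ", "),
             " are themselves amputed in the same pass", call. = FALSE)
    }
    entries[[nm]] <- e
  }
  structure(entries, class = "missingness_config")
}

# Numeric driver column (categoricals by category index), standardised.
driver_column <- function(table, nm) {
  x <- table$data[[nm]]
  if (is.character(x))
    x <- as.integer(factor(x, levels = table$schema[[nm]]$categories))
  x <- as.numeric(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) s <- 1
  (x - mean(x)) / s
}

# Calibrate the amputation-model intercept so mean(expit(a + score)) = rate.
calibrate_mar_intercept <- function(score, rate) {
  f <- function(a) mean(expit(a + score)) - rate
  lo <- -35; hi <- 35
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-10) break
  }
  (lo + hi) / 2
}

#' Ampute a complete table under configured mechanisms
#'
#' Masks cells of `table` according to a [missingness_config()]; observed
#' values are never altered, only hidden, so un-masking reproduces the input
#' exactly. Seed-reproducible.
#'
#' @param table a `cohort_table`, fully observed in every amputed column.
#' @param mconfig a `missingness_config`.
#' @param seed integer seed.
#' @return the amputed `cohort_table`.
#' @export
apply_missingness <- function(table, mconfig, seed = NULL) {
  stopifnot(inherits(mconfig, "missingness_config"))
  for (nm in names(mconfig))
    if (anyNA(table$data[[nm]]))
      stop("column '", nm, "' must be fully observed before amputation",
           call. = FALSE)
  with_seed(seed, {
    n <- n_participants(table)
    out <- table
    for (nm in names(mconfig)) {
      e <- mconfig[[nm]]
      if (e$rate == 0) next
      p <- if (e$mechanism == "MCAR") {
        rep(e$rate, n)
      } else {
        drivers <- if (e$mechanism == "MNAR") {
          stats::setNames(list(driver_column(table, nm)), nm)
        } else {
          lapply(stats::setNames(nm = names(e$dependence)),
                 function(d) driver_column(table, d))
        }
        w <- if (e$mechanism == "MNAR")
          (e$dependence %||% 1) else e$dependence
        score <- Reduce(`+`, Map(function(col, wt) wt * col,
                                 drivers, as.numeric(w)))
        a <- calibrate_mar_intercept(score, e$rate)
        expit(a + score)
      }
      hit <- stats::runif(n) < p
      out$data[[nm]][hit] <- NA
    }
    out
  })
}

#' Default configuration emulating the Bellville-South cohort
#'
#' Generator marginals follow the study's reported characteristics (age
#' 51.9 (15.0) years, BMI 29.7 (7.2) kg/m2, waist 95.8 (15.5) cm, SBP
#' 124.3 (20.2) and DBP 76.0 (12.9) mmHg; female 76.5%, antihypertensive
#' medication 35.4%, corticosteroids 1.2%, family-history prevalences
#' 7.5–15.3%, smoking current/past/no = 42.6/10.3/47.1%), with BMI–waist
#' and SBP–DBP coupled (rho 0.5 and 0.6). The outcome is drawn from a known
#' logistic model on age, BMI, waist circumference, maternal family history
#' and antihypertensive medication, with intercept set so that prevalence
#' matches the study's ~15%. Default missingness is MCAR at the study's
#' per-variable rates (family history ~25%, smoking 6.1%, outcome 0.7%,
#' others below 5%).
#'
#' @param n participant count (default 1083, the study's analysis sample).
#' @return list with elements `generator` (a `generator_config`) and
#'   `missingness` (a `missingness_config`).
#' @export
bellville_default_config <- function(n = 1083) {
  outcome_model <- risk_model_spec(
    "bellville_truth", intercept = -6.08,
    terms = list(
      model_term("age", 0.035),
      model_term("bmi", 0.040),
      model_term("waist_circumference", 0.010),
      model_term("fh_mother", 0.50),
      model_term("htn_medication", 0.40)
    ))
  gen <- generator_config(
    n = n,
    continuous = list(
      age = c(51.9, 15.0, 18, 95),
      bmi = c(29.7, 7.2, 12, 70),
      waist_circumference = c(95.8, 15.5, 40, 200),
      sbp = c(124.3, 20.2, 70, 260),
      dbp = c(76.0, 12.9, 40, 160)
    ),
    binary = c(gender = 0.765, fh_mother = 0.153, fh_father = 0.075,
               fh_sister = 0.127, fh_brother = 0.083,
               corticosteroids = 0.012, htn_medication = 0.354),
    categorical = list(
      smoking = c(current = 0.426, past = 0.103, no = 0.471)
    ),
    outcome_name = "undiagnosed_diabetes",
    outcome_model = outcome_model,
    correlation = list(
      list("bmi", "waist_circumference", 0.5),
      list("sbp", "dbp", 0.6)
    ),
    var_order = c("age", "gender", "bmi", "waist_circumference", "sbp",
                  "dbp", "fh_mother", "fh_father", "fh_sister",
                  "fh_brother", "corticosteroids", "htn_medication",
                  "smoking", "undiagnosed_diabetes")
  )
  rates <- c(undiagnosed_diabetes = 0.007, age = 0.014, gender = 0.016,
             bmi = 0.034, waist_circumference = 0.021, sbp = 0.019,
             dbp = 0.019, fh_mother = 0.251, fh_father = 0.249,
             fh_sister = 0.250, fh_brother = 0.251,
             corticosteroids = 0.043, htn_medication = 0.025,
             smoking = 0.061)
  miss <- missingness_config(
    lapply(stats::setNames(nm = names(rates)),
           function(nm) list(mechanism = "MCAR", rate = unname(rates[nm])))
  )
  list(generator = gen, missingness = miss)
}
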