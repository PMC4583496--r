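#' @name imputation
#' @title Missing-data handling strategies
#'
#' @description
#' Five strategies for handling missing cohort data before model validation:
#' complete-case deletion, unconditional mean/mode ("simple") imputation,
#' conditional mean imputation, stochastic regression imputation, and
#' multiple imputation by chained equations (fully conditional
#' specification). Single-imputation methods return an `imputed_dataset`;
#' multiple imputation returns a `multiple_imputation_result` holding m
#' completed datasets. No method ever modifies an observed cell.
NULL

new_imputed_dataset <- function(table, method, imputed_mask, log = character()) {
  eff <- colSums(!is.na(table$data))
  structure(
    list(table = table, method = method, imputed_mask = imputed_mask,
         effective_n = eff, log = log),
    class = "imputed_dataset"
  )
}

#' @export
print.imputed_dataset <- function(x, ...) {
  cat("<imputed_dataset> method '", x$method, "': n = ",
      n_participants(x$table), ", filled cells = ", sum(x$imputed_mask),
      if (length(x$log)) paste0(", ", length(x$log), " fallback(s)") else "",
      "\n", sep = "")
  invisible(x)
}

#' Complete-case deletion
#'
#' Retains exactly the rows with no missing value in any of the considered
#' variables; cell values are never changed. Reported under the method
#' label `"deletion"`.
#'
#' @param table a `cohort_table`.
#' @param variables variables whose completeness is required (default: all).
#' @return an `imputed_dataset` with `method = "deletion"`.
#' @export
complete_case <- function(table, variables = NULL) {
  variables <- variables %||% names(table$data)
  keep <- rowSums(is.na(table$data[, variables, drop = FALSE])) == 0
  out <- table
  out$data <- table$data[keep, , drop = FALSE]
  rownames(out$data) <- NULL
  log <- character()
  if (!any(keep)) log <- "deletion left zero complete rows"
  mask <- matrix(FALSE, nrow(out$data), ncol(out$data),
                 dimnames = list(NULL, names(out$data)))
  new_imputed_dataset(out, "deletion", mask, log)
}

# Mean fill for continuous, observed-mode fill for binary/categorical
# (ties broken by first category in schema order).
unconditional_fill_value <- function(x, vspec) {
  if (vspec$kind == "continuous") return(mean(x, na.rm = TRUE))
  lv <- if (vspec$kind == "binary") c("0", "1") else vspec$categories
  md <- observed_mode(as.character(x), lv)
  if (vspec$kind == "binary") as.integer(md) else md
}

#' Unconditional mean/mode imputation
#'
#' Fills every missing continuous cell with the observed column mean and
#' every missing binary/categorical cell with the observed majority
#' category. Column means are preserved exactly and sample SDs never
#' increase.
#'
#' @param table a `cohort_table`; every variable needs >= 1 observed value.
#' @return an `imputed_dataset` with `method = "simple"` and no residual
#'   missingness.
#' @export
simple_impute <- function(table) {
  mask <- missing_mask(table)
  out <- table
  for (v in table$schema) {
    miss <- mask[, v$name]
    if (!any(miss)) next
    if (all(miss))
      stop("cannot impute column '", v$name, "': no observed values",
           call. = FALSE)
    out$data[[v$name]][miss] <-
      unconditional_fill_value(table$data[[v$name]], v)
  }
  new_imputed_dataset(out, "simple", mask)
}

# ---- conditional model machinery ----------------------------------------

# Data frame with categoricals as factors (schema levels), for model fits.
model_frame <- function(data, schema) {
  for (v in schema)
    if (v$kind == "categorical")
      data[[v$name]] <- factor(data[[v$name]], levels = v$categories)
  data
}

# Fit the type-appropriate conditional model of `target` on all other
# variables, using rows `fit_rows` of `mf`. Returns NULL on failure.
fit_conditional <- function(mf, target, vspec, fit_rows) {
  preds <- setdiff(names(mf), target)
  # drop predictors constant on the fitting rows (would make fits singular)
  keep <- vapply(preds, function(p) {
    x <- mf[[p]][fit_rows]
    length(unique(x[!is.na(x)])) > 1
  }, logical(1))
  preds <- preds[keep]
  if (!length(preds)) return(NULL)
  fml <- stats::as.formula(paste(target, "~",
                                 paste(preds, collapse = " + ")))
  fit <- tryCatch(switch(vspec$kind,
    continuous = stats::lm(fml, data = mf[fit_rows, , drop = FALSE]),
    binary = suppressWarnings(
      stats::glm(fml, data = mf[fit_rows, , drop = FALSE],
                 family = stats::binomial())),
    categorical = {
      # multinom draws random starting weights; fit under a fixed local
      # RNG state so a deterministic method stays deterministic
      capture <- utils::capture.output(
        m <- with_seed(0L,
          nnet::multinom(fml, data = mf[fit_rows, , drop = FALSE],
                         maxit = 200)))
      m
    }), error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  list(fit = fit, kind = vspec$kind, target = target)
}

# Prediction from a conditional fit, NULL if prediction itself fails
# (e.g. a factor level absent from the fitting rows).
try_predict_conditional <- function(cm, mf, rows, type) {
  if (is.null(cm)) return(NULL)
  tryCatch(predict_conditional(cm, mf, rows, type),
           error = function(e) NULL)
}

# Prediction from a conditional fit for rows `rows` of `mf`.
# type = "mean": deterministic (conditional mean / most probable class).
# type = "draw": stochastic (prediction + residual-noise draw / class draw)
#   with no parameter-uncertainty draw (regression coefficients are used as
#   estimated: the norm.nob semantics of single stochastic imputation).
# type = "bayes": proper-imputation draw for the chained-equations method —
#   continuous: sigma^2* from the scaled inverse-chi-square posterior and
#   beta* ~ N(beta_hat, sigma^2* (X'X)^-1) before the residual draw;
#   binary: beta* ~ N(beta_hat, vcov) before the Bernoulli draw;
#   categorical falls back to class-probability draws.
predict_conditional <- function(cm, mf, rows, type) {
  nd <- mf[rows, , drop = FALSE]
  if (cm$kind == "continuous") {
    if (type == "bayes") {
      bd <- bayes_lm_draw(cm$fit, nd)
      if (!is.null(bd)) return(bd)
      # fall through to the plain residual draw on failure
    }
    mu <- as.numeric(stats::predict(cm$fit, newdata = nd))
    if (type == "mean") return(mu)
    rdf <- cm$fit$df.residual
    sigma <- if (rdf > 0)
      sqrt(sum(stats::residuals(cm$fit)^2) / rdf) else 0
    return(mu + stats::rnorm(length(mu), 0, sigma))
  }
  if (cm$kind == "binary") {
    if (type == "bayes") {
      bp <- bayes_glm_draw(cm$fit, nd)
      if (!is.null(bp)) return(stats::rbinom(length(bp), 1, bp))
    }
    p <- as.numeric(stats::predict(cm$fit, newdata = nd,
                                   type = "response"))
    if (type == "mean") return(as.integer(p > 0.5))
    return(stats::rbinom(length(p), 1, p))
  }
  pr <- stats::predict(cm$fit, newdata = nd, type = "probs")
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = nrow(nd))
  lv <- cm$fit$lev
  if (type == "mean") return(lv[max.col(pr, ties.method = "first")])
  vapply(seq_len(nrow(pr)), function(i)
    sample(lv, 1, prob = pr[i, ]), character(1))
}

# One posterior draw from a fitted linear model, evaluated on new data:
# sigma^2* = RSS / chi2(df), beta* ~ N(beta_hat, sigma^2* (X'X)^-1),
# returned as X beta* + N(0, sigma*) — the standard Bayesian linear
# regression imputation draw. NULL if the design matrix cannot be rebuilt.
bayes_lm_draw <- function(fit, nd) {
  tryCatch({
    co <- stats::coef(fit)
    ok <- !is.na(co)
    tt <- stats::delete.response(stats::terms(fit))
    X <- stats::model.matrix(tt, nd, xlev = fit$xlevels)[, ok, drop = FALSE]
    rdf <- fit$df.residual
    rss <- sum(stats::residuals(fit)^2)
    if (rdf <= 0 || rss <= 0) return(NULL)
    sigma2 <- rss / stats::rchisq(1, rdf)
    v <- stats::vcov(fit)[ok, ok, drop = FALSE] /
      (rss / rdf) * sigma2                      # sigma^2* (X'X)^-1
    beta <- co[ok] + drop(crossprod(chol(v), stats::rnorm(sum(ok))))
    drop(X %*% beta) + stats::rnorm(nrow(X), 0, sqrt(sigma2))
  }, error = function(e) NULL)
}

# One approximate posterior draw from a fitted logistic model: beta* from
# the large-sample normal N(beta_hat, vcov), returning fitted probabilities
# on new data. NULL on failure.
bayes_glm_draw <- function(fit, nd) {
  tryCatch({
    co <- stats::coef(fit)
    ok <- !is.na(co)
    tt <- stats::delete.response(stats::terms(fit))
    X <- stats::model.matrix(tt, nd, xlev = fit$xlevels)[, ok, drop = FALSE]
    v <- stats::vcov(fit)[ok, ok, drop = FALSE]
    beta <- co[ok] + drop(crossprod(chol(v), stats::rnorm(sum(ok))))
    expit(drop(X %*% beta))
  }, error = function(e) NULL)
}

# Coerce predicted values back to storage type.
coerce_fill <- function(x, vspec) {
  switch(vspec$kind,
    continuous = as.numeric(x),
    binary = as.integer(x),
    categorical = as.character(x))
}

#' Conditional mean imputation
#'
#' For each variable with missing values, fits a regression of that
#' variable on all other variables (outcome included) using the fully
#' complete rows — a linear model for continuous targets, logistic for
#' binary (filled with the most probable class), multinomial for
#' categorical — and fills only those missing cells whose row is complete
#' on every predictor. Rows missing a predictor keep their missing cell, so
#' the completed columns have varied effective lengths.
#'
#' @param table a `cohort_table`.
#' @return an `imputed_dataset` with `method = "conditional"`; residual
#'   missingness is permitted.
#' @export
conditional_mean_impute <- function(table) {
  mask <- missing_mask(table)
  mf <- model_frame(table$data, table$schema)
  complete_rows <- rowSums(mask) == 0
  out <- table
  filled <- mask & FALSE
  log <- character()
  for (v in table$schema) {
    nm <- v$name
    miss <- mask[, nm]
    if (!any(miss)) next
    # fillable rows: target missing, every other variable observed
    others <- setdiff(colnames(mask), nm)
    fillable <- miss & rowSums(mask[, others, drop = FALSE]) == 0
    if (!any(fillable)) next
    cm <- if (sum(complete_rows) >= ncol(mask) + 2)
      fit_conditional(mf, nm, v, complete_rows) else NULL
    pred <- try_predict_conditional(cm, mf, fillable, "mean")
    if (is.null(pred)) {
      log <- c(log, paste0("conditional fit failed for '", nm,
                           "'; unconditional mean/mode fallback"))
      out$data[[nm]][fillable] <-
        unconditional_fill_value(table$data[[nm]], v)
    } else {
      out$data[[nm]][fillable] <- coerce_fill(pred, v)
    }
    filled[fillable, nm] <- TRUE
  }
  new_imputed_dataset(out, "conditional", filled, log)
}

# One fully-conditional-specification sweep over `targets` (a logical cell
# mask of cells to redraw). Fits each variable's stochastic conditional
# model on the rows where that variable was originally observed, with all
# other variables (currently completed) as predictors, then redraws the
# target cells. Returns the updated model frame and a fallback log.
fcs_sweep <- function(mf, schema, targets, observed_rows, log,
                      type = "draw") {
  for (v in schema) {
    nm <- v$name
    cells <- targets[, nm]
    if (!any(cells)) next
    cm <- fit_conditional(mf, nm, v, observed_rows[, nm])
    draw <- try_predict_conditional(cm, mf, cells, type)
    if (is.null(draw)) {
      log <- c(log, paste0("FCS fit failed for '", nm,
                           "'; observed-value draw fallback"))
      obs <- mf[[nm]][observed_rows[, nm]]
      mf[[nm]][cells] <- sample(obs, sum(cells), replace = TRUE)
    } else {
      mf[[nm]][cells] <- if (v$kind == "categorical")
        factor(draw, levels = v$categories) else coerce_fill(draw, v)
    }
  }
  list(mf = mf, log = log)
}

# Initialise target cells with random draws from the observed values.
fcs_initialise <- function(mf, schema, targets, observed_rows) {
  for (v in schema) {
    nm <- v$name
    cells <- targets[, nm]
    if (!any(cells)) next
    obs <- mf[[nm]][observed_rows[, nm]]
    mf[[nm]][cells] <- sample(obs, sum(cells), replace = TRUE)
  }
  mf
}

model_frame_to_data <- function(mf, schema) {
  for (v in schema)
    if (v$kind == "categorical")
      mf[[v$name]] <- as.character(mf[[v$name]])
  mf
}

#' Stochastic regression imputation
#'
#' Single stochastic imputation with regression-plus-noise semantics:
#' continuous fills are the conditional-model prediction plus a residual
#' draw `rnorm(0, sigma_hat)` (no parameter-uncertainty draw), binary and
#' categorical fills are drawn from the fitted class probabilities. Cells
#' whose row is complete on all predictors are filled from models fitted on
#' the fully complete rows; remaining cells are completed by one chained
#' (fully conditional) pass seeded from unconditional observed-value draws,
#' so the output has no residual missingness.
#'
#' @param table a `cohort_table`.
#' @param seed integer seed; identical seeds give identical fills.
#' @return an `imputed_dataset` with `method = "stochastic"` and a fully
#'   observed table.
#' @export
stochastic_regression_impute <- function(table, seed = NULL) {
  mask <- missing_mask(table)
  with_seed(seed, {
    mf <- model_frame(table$data, table$schema)
    complete_rows <- rowSums(mask) == 0
    observed_rows <- !mask
    log <- character()
    # pass 1: direct regression draws where the predictors are complete
    for (v in table$schema) {
      nm <- v$name
      miss <- mask[, nm]
      if (!any(miss)) next
      others <- setdiff(colnames(mask), nm)
      fillable <- miss & rowSums(mask[, others, drop = FALSE]) == 0
      if (!any(fillable)) next
      cm <- if (sum(complete_rows) >= ncol(mask) + 2)
        fit_conditional(mf, nm, v, complete_rows) else NULL
      draw <- try_predict_conditional(cm, mf, fillable, "draw")
      if (is.null(draw)) {
        log <- c(log, paste0("stochastic fit failed for '", nm,
                             "'; observed-value draw fallback"))
        obs <- mf[[nm]][observed_rows[, nm]]
        mf[[nm]][fillable] <- sample(obs, sum(fillable), replace = TRUE)
      } else {
        mf[[nm]][fillable] <- if (v$kind == "categorical")
          factor(draw, levels = v$categories) else coerce_fill(draw, v)
      }
    }
    # pass 2: one FCS sweep for cells whose rows were incomplete on predictors
    leftover <- mask & is.na(as.matrix(
      model_frame_to_data(mf, table$schema)[colnames(mask)]))
    if (any(leftover)) {
      mf <- fcs_initialise(mf, table$schema, leftover, observed_rows)
      sw <- fcs_sweep(mf, table$schema, leftover, observed_rows, log)
      mf <- sw$mf; log <- sw$log
    }
    out <- table
    out$data <- model_frame_to_data(mf, table$schema)
    new_imputed_dataset(out, "stochastic", mask, log)
  })
}

#' Multiple imputation by chained equations
#'
#' Fully conditional specification: missing cells are initialised with
#' random draws from each variable's observed values, then the variables
#' are cycled in schema order for `iterations` sweeps; each visit refits
#' the type-appropriate stochastic conditional model (continuous: linear
#' regression with posterior draws of the coefficients and residual
#' variance before the residual-noise draw, so the imputation is proper;
#' binary: logistic with a large-sample posterior coefficient draw plus a
#' Bernoulli draw; categorical: multinomial plus categorical draw) on the
#' rows where
#' the variable was originally observed, with all other variables as
#' currently completed serving as predictors (the outcome included), and
#' redraws the variable's originally-missing cells. The whole chain is
#' repeated m times with independent sub-seeds.
#'
#' @param table a `cohort_table`.
#' @param m number of imputed datasets (>= 2).
#' @param iterations number of sweeps per chain.
#' @param seed integer master seed; identical inputs give bit-identical
#'   results.
#' @return object of class `multiple_imputation_result`: list with
#'   `datasets` (m `imputed_dataset`s, method `"mice"`), `m`, `iterations`,
#'   `seed`.
#' @export
mice_impute <- function(table, m = 5, iterations = 10, seed = 1) {
  if (m < 2) stop("multiple imputation needs m >= 2", call. = FALSE)
  mask <- missing_mask(table)
  for (v in table$schema)
    if (any(mask[, v$name]) && all(mask[, v$name]))
      stop("cannot impute column '", v$name, "': no observed values",
           call. = FALSE)
  observed_rows <- !mask
  datasets <- vector("list", m)
  for (k in seq_len(m)) {
    if (!any(mask)) {
      datasets[[k]] <- new_imputed_dataset(table, "mice", mask)
      next
    }
    sub <- derive_seed(seed, "mice", k)
    datasets[[k]] <- with_seed(sub, {
      mf <- model_frame(table$data, table$schema)
      mf <- fcs_initialise(mf, table$schema, mask, observed_rows)
      log <- character()
      for (it in seq_len(iterations)) {
        sw <- fcs_sweep(mf, table$schema, mask, observed_rows, log,
                        type = "bayes")
        mf <- sw$mf; log <- sw$log
      }
      out <- table
      out$data <- model_frame_to_data(mf, table$schema)
      new_imputed_dataset(out, "mice", mask, unique(log))
    })
  }
  structure(list(datasets = datasets, m = m, iterations = iterations,
                 seed = seed),
            class = "multiple_imputation_result")
}

#' @export
print.multiple_imputation_result <- function(x, ...) {
  cat("<multiple_imputation_result> m = ", x$m, ", iterations = ",
      x$iterations, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Serialise a multiple-imputation result
#'
#' Writes one CSV per completed dataset plus a small YAML manifest
#' (m, seed, iterations).
#'
#' @param result a `multiple_imputation_result`.
#' @param dir destination directory (created if needed).
#' @return character vector of file paths, invisibly.
#' @export
write_mi_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_len(result$m), function(k) {
    p <- file.path(dir, sprintf("imputed_%02d.csv", k))
    write_cohort(result$datasets[[k]]$table, p)
    p
  }, character(1))
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(m = result$m, seed = result$seed,
                        iterations = result$iterations), manifest)
  invisible(c(paths, manifest))
}

#' Pool estimates across imputed datasets by Rubin's rules
#'
#' Combines m per-imputation estimates and their variances: the pooled
#' point estimate is the arithmetic mean `q_bar`; the within-imputation
#' variance `w` is the mean of the per-dataset variances; the
#' between-imputation variance `b` is the sample variance (divisor m - 1)
#' of the estimates; the total variance is `t = w + (1 + 1/m) b`; and the
#' large-sample degrees of freedom are
#' `df = (m - 1) (1 + w / ((1 + 1/m) b))^2` (infinite when `b = 0`).
#'
#' @param estimates numeric vector of m >= 2 per-imputation estimates.
#' @param variances numeric vector of m matching variances (>= 0).
#' @return object of class `pooled_estimate`: list with `q_bar`, `w`, `b`,
#'   `t`, `df`, `m`.
#' @export
rubin_pool <- function(estimates, variances) {
  m <- length(estimates)
  if (m < 2 || length(variances) != m)
    stop("need equal-length estimate/variance vectors with m >= 2",
         call. = FALSE)
  if (any(variances < 0)) stop("variances must be >= 0", call. = FALSE)
  q_bar <- mean(estimates)
  w <- mean(variances)
  b <- stats::var(estimates)
  t <- w + (1 + 1 / m) * b
  df <- if (b == 0) Inf else (m - 1) * (1 + w / ((1 + 1 / m) * b))^2
  structure(list(q_bar = q_bar, w = w, b = b, t = t, df = df, m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "<pooled_estimate> q_bar = %.6g (w = %.3g, b = %.3g, t = %.3g, df = %s, m = %d)\n",
    x$q_bar, x$w, x$b, x$t, format(round(x$df, 1)), x$m))
  invisible(x)
}

#' Run one imputation method by name
#'
#' Dispatch helper used by the benchmarking pipeline: accepts the method
#' labels `deletion`, `simple`, `conditional`, `stochastic`, `mice`.
#'
#' @param table a `cohort_table`.
#' @param method method label.
#' @param m,iterations multiple-imputation settings (mice only).
#' @param seed integer seed for the stochastic methods.
#' @return an `imputed_dataset`, or a `multiple_imputation_result` for
#'   `method = "mice"`.
#' @export
impute_method <- function(table, method, m = 5, iterations = 10,
                          seed = 1) {
  method <- match.arg(method, c("deletion", "simple", "conditional",
                                "stochastic", "mice"))
  switch(method,
    deletion = complete_case(table),
    simple = simple_impute(table),
    conditional = conditional_mean_impute(table),
    stochastic = stochastic_regression_impute(
      table, derive_seed(seed, "stochastic")),
    mice = mice_impute(table, m = m, iterations = iterations, seed = seed))
}
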