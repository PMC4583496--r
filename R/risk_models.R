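#' Declarative logistic risk models
#'
#' A risk model is an intercept plus additive terms on the logit scale:
#' `lp = intercept + sum(coefficient * transform(value))`, with predicted
#' probability `expit(lp)`. Transforms cover the constructions used by
#' published non-invasive diabetes scores:
#'
#' * `identity` — the raw value (binary variables contribute their 0/1 code);
#' * `indicator(category)` — 1 when the value equals the category;
#' * `band(breaks, scores)` — a step function: `scores[k]` when the value
#'   falls in the k-th interval of the strictly increasing `breaks`
#'   (left-open intervals, `length(scores) == length(breaks) + 1`);
#' * `product` — the product of simple component transforms, for
#'   interaction terms.
#'
#' @param name model label, unique within a registry.
#' @param intercept real intercept on the logit scale.
#' @param terms list of terms, each created by [model_term()].
#' @return object of class `risk_model_spec`.
#' @export
risk_model_spec <- function(name, intercept, terms = list()) {
  stopifnot(is.character(name), length(name) == 1,
            is.numeric(intercept), length(intercept) == 1)
  for (tm in terms) validate_term(tm)
  structure(list(name = name, intercept = as.numeric(intercept),
                 terms = terms),
            class = "risk_model_spec")
}

#' Build one additive model term
#'
#' @param variable variable name the term reads (ignored for `product`).
#' @param coefficient real multiplier.
#' @param transform transform type: `"identity"`, `"indicator"`, `"band"`
#'   or `"product"`.
#' @param category category label (indicator only).
#' @param breaks strictly increasing numeric cut points (band only).
#' @param scores numeric level scores, one more than `breaks` (band only).
#' @param components for `product`: list of sub-terms (each a [model_term()]
#'   with transform `identity`, `indicator` or `band` and coefficient 1).
#' @return a term list suitable for [risk_model_spec()].
#' @export
model_term <- function(variable = NULL, coefficient = 1,
                       transform = c("identity", "indicator", "band",
                                     "product"),
                       category = NULL, breaks = NULL, scores = NULL,
                       components = NULL) {
  transform <- match.arg(transform)
  tm <- list(variable = variable, coefficient = as.numeric(coefficient),
             transform = transform, category = category,
             breaks = breaks, scores = scores, components = components)
  validate_term(tm)
  tm
}

validate_term <- function(tm) {
  if (!is.list(tm) || is.null(tm$transform))
    stop("malformed model term (no transform)", call. = FALSE)
  if (!tm$transform %in% c("identity", "indicator", "band", "product"))
    stop("unknown transform kind '", tm$transform, "'", call. = FALSE)
  if (!is.numeric(tm$coefficient) || length(tm$coefficient) != 1 ||
      !is.finite(tm$coefficient))
    stop("term coefficient must be a finite number", call. = FALSE)
  if (tm$transform == "product") {
    if (is.null(tm$components) || length(tm$components) < 2)
      stop("product term needs >= 2 components", call. = FALSE)
    for (cm in tm$components) {
      if (identical(cm$transform, "product"))
        stop("product terms cannot nest", call. = FALSE)
      validate_term(cm)
    }
  } else {
    if (is.null(tm$variable))
      stop("term needs a variable", call. = FALSE)
    if (tm$transform == "indicator" && is.null(tm$category))
      stop("indicator term needs a category", call. = FALSE)
    if (tm$transform == "band") {
      if (is.null(tm$breaks) || is.null(tm$scores))
        stop("band term needs breaks and scores", call. = FALSE)
      if (length(tm$breaks) >= 2 && any(diff(tm$breaks) <= 0))
        stop("band breaks must be strictly increasing", call. = FALSE)
      if (length(tm$scores) != length(tm$breaks) + 1)
        stop("band needs length(scores) == length(breaks) + 1", call. = FALSE)
    }
  }
  invisible(tm)
}

term_variables <- function(tm) {
  if (tm$transform == "product")
    unlist(lapply(tm$components, term_variables))
  else
    tm$variable
}

#' Variables a model requires
#' @param model a `risk_model_spec`.
#' @return character vector of variable names.
#' @export
model_variables <- function(model) {
  unique(unlist(lapply(model$terms, term_variables)))
}

# Evaluate one term on a data.frame; returns the coefficient * transform
# value per row (NA where the inputs are missing).
eval_term <- function(tm, data) {
  val <- switch(tm$transform,
    identity = as.numeric(data[[tm$variable]]),
    indicator = as.numeric(data[[tm$variable]] == tm$category),
    band = {
      x <- as.numeric(data[[tm$variable]])
      idx <- findInterval(x, tm$breaks) + 1L
      out <- rep(NA_real_, length(x))
      ok <- !is.na(idx)
      out[ok] <- tm$scores[idx[ok]]
      out
    },
    product = {
      vals <- lapply(tm$components, eval_term, data = data)
      Reduce(`*`, vals)
    })
  tm$coefficient * val
}

#' Linear predictor of a risk model
#' @param model a `risk_model_spec`.
#' @param data data.frame of predictor values.
#' @return numeric vector (NA where a required predictor is missing).
#' @export
linear_predictor <- function(model, data) {
  lp <- rep(model$intercept, nrow(data))
  for (tm in model$terms) lp <- lp + eval_term(tm, data)
  lp
}

#' Score a cohort with a risk model
#'
#' Computes each participant's predicted outcome probability. Rows missing
#' any required predictor are counted as unscorable and get `NA` — they are
#' never silently scored with partial information.
#'
#' @param model a `risk_model_spec`.
#' @param table a `cohort_table` (or plain data.frame).
#' @return object of class `risk_predictions`: list with `probability`
#'   (length n, NA where unscorable), `linear_predictor`, `model`,
#'   `n_scored`, `n_unscorable`, `scorable` (logical index).
#' @export
predict_risk <- function(model, table) {
  data <- if (inherits(table, "cohort_table")) table$data else table
  need <- model_variables(model)
  absent <- setdiff(need, names(data))
  if (length(absent))
    stop("model '", model$name, "' needs absent variable(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  lp <- linear_predictor(model, data)
  prob <- ifelse(is.na(lp), NA_real_, expit(lp))
  scorable <- !is.na(lp)
  structure(
    list(probability = prob, linear_predictor = lp, model = model$name,
         n_scored = sum(scorable), n_unscorable = sum(!scorable),
         scorable = scorable),
    class = "risk_predictions"
  )
}

#' @export
print.risk_predictions <- function(x, ...) {
  cat("<risk_predictions> model '", x$model, "': ", x$n_scored,
      " scored, ", x$n_unscorable, " unscorable\n", sep = "")
  if (x$n_scored > 0) {
    p <- x$probability[x$scorable]
    cat(sprintf("  probability: min %.3f / median %.3f / max %.3f\n",
                min(p), stats::median(p), max(p)))
  }
  invisible(x)
}

#' @rdname predict_risk
#' @param object a `risk_model_spec`.
#' @param newdata cohort table or data.frame to score.
#' @param ... unused.
#' @export
predict.risk_model_spec <- function(object, newdata, ...) {
  predict_risk(object, newdata)
}

#' @export
print.risk_model_spec <- function(x, ...) {
  cat("<risk_model_spec> '", x$name, "': intercept ", format(x$intercept),
      ", ", length(x$terms), " terms on ",
      paste(model_variables(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Recalibrate a model's intercept to a validation cohort
#'
#' Adds a constant `delta` to the linear predictor so that the expected
#' event count equals the observed event count over the scorable rows with
#' an observed outcome (mean calibration, E/O = 1). `delta` is found by
#' bisection on \[-20, 20\]; the expected count is continuous and strictly
#' increasing in `delta`, and the search stops at `|E - O| <= 1e-6 * O`.
#' The shift is rank-preserving, so discrimination is untouched.
#'
#' @param model a `risk_model_spec`.
#' @param table a `cohort_table` whose outcome is observed on scored rows.
#' @return the recalibrated `risk_model_spec` with attribute `"delta"`.
#' @export
recalibrate_intercept <- function(model, table) {
  preds <- predict_risk(model, table)
  y <- table$data[[table$outcome_name]]
  use <- preds$scorable & !is.na(y)
  lp <- preds$linear_predictor[use]
  o <- sum(y[use])
  if (o < 1 || o >= sum(use))
    stop("recalibration needs >=1 event and >=1 non-event", call. = FALSE)
  f <- function(delta) sum(expit(lp + delta)) - o
  lo <- -20; hi <- 20
  if (f(lo) > 0 || f(hi) < 0)
    stop("recalibration root not bracketed in [-20, 20]", call. = FALSE)
  tol <- 1e-6 * o
  repeat {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) <= tol || (hi - lo) < 1e-14) break
    if (fm > 0) hi <- mid else lo <- mid
  }
  out <- model
  out$intercept <- model$intercept + mid
  attr(out, "delta") <- mid
  out
}

# ---- serialisation -------------------------------------------------------

term_to_list <- function(tm) {
  out <- list(variable = tm$variable, coefficient = tm$coefficient,
              transform = tm$transform)
  if (tm$transform == "indicator") out$category <- tm$category
  if (tm$transform == "band") {
    out$breaks <- tm$breaks; out$scores <- tm$scores
  }
  if (tm$transform == "product")
    out$components <- lapply(tm$components, term_to_list)
  out[!vapply(out, is.null, logical(1))]
}

term_from_list <- function(x) {
  model_term(
    variable = x$variable,
    coefficient = if (is.null(x$coefficient)) 1 else x$coefficient,
    transform = if (is.null(x$transform)) "identity" else x$transform,
    category = x$category,
    breaks = unlist(x$breaks), scores = unlist(x$scores),
    components = if (!is.null(x$components))
      lapply(x$components, term_from_list)
  )
}

#' Save a risk model specification to a YAML file
#' @param model a `risk_model_spec`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
save_model_spec <- function(model, path) {
  obj <- list(name = model$name, intercept = model$intercept,
              link = "logistic",
              terms = lapply(model$terms, term_to_list))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Load a risk model specification from a YAML file
#'
#' Validates the spec on load: unknown transform kinds, non-increasing band
#' breaks or mismatched score lengths are rejected with a descriptive error.
#'
#' @param path file path of a model spec.
#' @return a `risk_model_spec`.
#' @export
load_model_spec <- function(path) {
  if (!file.exists(path)) stop("model spec not found: ", path, call. = FALSE)
  obj <- yaml::read_yaml(path)
  if (is.null(obj$name) || is.null(obj$intercept))
    stop("model spec ", path, " lacks name or intercept", call. = FALSE)
  if (!is.null(obj$link) && !identical(obj$link, "logistic"))
    stop("unsupported link '", obj$link, "' (only logistic)", call. = FALSE)
  terms <- lapply(obj$terms, term_from_list)
  risk_model_spec(obj$name, obj$intercept, terms)
}

#' Built-in registry of published diabetes risk model structures
#'
#' Loads the five shipped non-invasive undiagnosed-diabetes model
#' specifications (Cambridge, Kuwaiti, Omani, Rotterdam, simplified
#' Finnish). Every spec includes an age term, and predictor sets follow the
#' published model structures; the shipped coefficients are PLACEHOLDER
#' values of plausible sign and magnitude, intended to be replaced by the
#' exact published coefficients from the original model publications —
#' edit the YAML files or point `dir` at your own.
#'
#' @param dir directory of model spec YAML files (defaults to the
#'   installed copies).
#' @return named list of `risk_model_spec` objects.
#' @export
builtin_registry <- function(dir = system.file("extdata", "models",
                                               package = "missbench")) {
  expected <- c("cambridge", "kuwaiti", "omani", "rotterdam",
                "finnish_simplified")
  paths <- file.path(dir, paste0(expected, ".yaml"))
  absent <- expected[!file.exists(paths)]
  if (length(absent))
    stop("registry is missing model spec file(s): ",
         paste(paste0(absent, ".yaml"), collapse = ", "), call. = FALSE)
  specs <- lapply(paths, load_model_spec)
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}
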