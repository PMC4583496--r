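#' Concordance statistic with nonparametric confidence interval
#'
#' The C-statistic is the probability that a randomly chosen event carries
#' a higher predicted risk than a randomly chosen non-event, with ties
#' counting one half. Computed through the midrank (Mann-Whitney)
#' identity, which equals exhaustive pair enumeration exactly; the 95%
#' confidence interval uses the DeLong placement-value variance by default
#' (Hanley-McNeil available for sensitivity analyses), truncated to
#' \[0, 1\].
#'
#' @param predictions numeric vector of predicted probabilities (or any
#'   risk scores — the statistic is rank-based).
#' @param outcomes 0/1 vector of observed outcomes, same length.
#' @param ci_method `"delong"` (default) or `"hanley"`.
#' @return list with `c`, `ci` (length-2), `var` (variance of `c`).
#' @export
c_statistic <- function(predictions, outcomes, ci_method = c("delong",
                                                             "hanley")) {
  ci_method <- match.arg(ci_method)
  keep <- !is.na(predictions) & !is.na(outcomes)
  p <- predictions[keep]; y <- outcomes[keep]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 < 1 || n0 < 1)
    stop("C-statistic needs >= 1 event and >= 1 non-event", call. = FALSE)
  r_all <- rank(p, ties.method = "average")
  cstat <- (sum(r_all[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (ci_method == "delong") {
    r1 <- rank(p[y == 1], ties.method = "average")
    r0 <- rank(p[y == 0], ties.method = "average")
    v10 <- (r_all[y == 1] - r1) / n0          # event placements
    v01 <- 1 - (r_all[y == 0] - r0) / n1      # non-event placements
    vr <- (if (n1 > 1) stats::var(v10) / n1 else 0) +
      (if (n0 > 1) stats::var(v01) / n0 else 0)
  } else {
    q1 <- cstat / (2 - cstat)
    q2 <- 2 * cstat^2 / (1 + cstat)
    vr <- (cstat * (1 - cstat) + (n1 - 1) * (q1 - cstat^2) +
             (n0 - 1) * (q2 - cstat^2)) / (n1 * n0)
  }
  half <- 1.96 * sqrt(max(vr, 0))
  list(c = cstat, ci = c(max(0, cstat - half), min(1, cstat + half)),
       var = vr)
}

#' Brier score
#'
#' Mean squared difference between predicted probability and observed 0/1
#' outcome: 0 for a perfect model, up to 1 for total disagreement.
#'
#' @inheritParams c_statistic
#' @return a single number in \[0, 1\].
#' @export
brier_score <- function(predictions, outcomes) {
  keep <- !is.na(predictions) & !is.na(outcomes)
  if (!any(keep)) stop("Brier score needs >= 1 scored row", call. = FALSE)
  mean((predictions[keep] - outcomes[keep])^2)
}

#' Yates (discrimination) slope
#'
#' Difference between the mean predicted probability of events and of
#' non-events; larger is better.
#'
#' @inheritParams c_statistic
#' @return a single number in \[-1, 1\].
#' @export
yates_slope <- function(predictions, outcomes) {
  keep <- !is.na(predictions) & !is.na(outcomes)
  p <- predictions[keep]; y <- outcomes[keep]
  if (sum(y == 1) < 1 || sum(y == 0) < 1)
    stop("Yates slope needs >= 1 event and >= 1 non-event", call. = FALSE)
  mean(p[y == 1]) - mean(p[y == 0])
}

#' Expected/observed ratio with Poisson confidence interval
#'
#' Mean calibration: the sum of predicted probabilities (expected events E)
#' over the observed event count O. The 95% interval treats O as Poisson on
#' the log scale: `ratio * exp(-1.96 / sqrt(O))` to
#' `ratio * exp(+1.96 / sqrt(O))`, which keeps both bounds positive.
#'
#' @inheritParams c_statistic
#' @return list with `ratio`, `ci` (length-2), `e`, `o`.
#' @export
expected_observed <- function(predictions, outcomes) {
  keep <- !is.na(predictions) & !is.na(outcomes)
  p <- predictions[keep]; y <- outcomes[keep]
  o <- sum(y)
  if (o < 1) stop("E/O ratio needs >= 1 observed event", call. = FALSE)
  e <- sum(p)
  ratio <- e / o
  half <- 1.96 / sqrt(o)
  list(ratio = ratio, ci = c(ratio * exp(-half), ratio * exp(half)),
       e = e, o = o)
}

#' Evaluate a set of predictions against observed outcomes
#'
#' Assembles the full performance panel (E/O ratio with Poisson interval,
#' Brier score, Yates slope, C-statistic with DeLong interval) on the
#' common scored-row subset: rows with both a prediction and an observed
#' outcome.
#'
#' @param predictions a `risk_predictions` object or numeric probability
#'   vector.
#' @param outcomes 0/1 outcome vector (taken from the scored table by the
#'   pipeline).
#' @param state calibration state label, `"original"` or `"adjusted"`.
#' @param model,method optional labels carried into the report.
#' @return object of class `performance_report`.
#' @export
evaluate_performance <- function(predictions, outcomes,
                                 state = c("original", "adjusted"),
                                 model = NA_character_,
                                 method = NA_character_) {
  state <- match.arg(state)
  if (inherits(predictions, "risk_predictions")) {
    if (is.na(model)) model <- predictions$model
    predictions <- predictions$probability
  }
  keep <- !is.na(predictions) & !is.na(outcomes)
  p <- predictions[keep]; y <- outcomes[keep]
  failing <- character()
  if (length(p) < 1) failing <- c(failing, "all (no scored rows)")
  else {
    if (sum(y == 1) < 1)
      failing <- c(failing, "C-statistic/Yates slope/E-O (no events)")
    if (sum(y == 0) < 1)
      failing <- c(failing, "C-statistic/Yates slope (no non-events)")
  }
  if (length(failing))
    stop("degenerate outcome vector; cannot compute: ",
         paste(failing, collapse = "; "), call. = FALSE)
  cs <- c_statistic(p, y)
  eo <- expected_observed(p, y)
  structure(
    list(model = model, method = method, state = state,
         e = eo$e, o = eo$o, eo_ratio = eo$ratio, eo_ci = eo$ci,
         brier = brier_score(p, y), yates_slope = yates_slope(p, y),
         c = cs$c, c_ci = cs$ci, c_var = cs$var, n_eff = length(p)),
    class = "performance_report"
  )
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf(
    paste0("<performance_report> %s / %s / %s (n = %d)\n",
           "  E/O %.2f (%.2f-%.2f)  Brier %.3f  Yates %.3f  C %.2f (%.2f-%.2f)\n"),
    x$model, x$method, x$state, x$n_eff,
    x$eo_ratio, x$eo_ci[1], x$eo_ci[2], x$brier, x$yates_slope,
    x$c, x$c_ci[1], x$c_ci[2]))
  invisible(x)
}

#' Pool performance reports across multiply imputed datasets
#'
#' Point estimates are pooled as the arithmetic mean across datasets
#' (Rubin's pooled estimate); confidence intervals are pooled through
#' Rubin's total variance on each metric's working scale — logit for the
#' C-statistic (variance by the delta method from the DeLong variance) and
#' log for the E/O ratio (Poisson variance 1/O) — with a t-quantile on the
#' Rubin degrees of freedom. Brier score and Yates slope are pooled as
#' plain means.
#'
#' @param reports list of m >= 2 `performance_report`s for the same model.
#' @param m number of imputations (defaults to `length(reports)`).
#' @return a pooled `performance_report` (method `"mice"` unless all
#'   reports agree on another label).
#' @export
pool_reports <- function(reports, m = length(reports)) {
  if (length(reports) < 2)
    stop("pooling needs >= 2 reports", call. = FALSE)
  models <- unique(vapply(reports, `[[`, character(1), "model"))
  if (length(models) > 1)
    stop("cannot pool reports from different models: ",
         paste(models, collapse = ", "), call. = FALSE)
  g <- function(f) vapply(reports, `[[`, numeric(1), f)
  # zero between-imputation variance: pooling is the identity
  identical_reports <- all(vapply(
    c("c", "eo_ratio", "brier", "yates_slope", "e", "o"),
    function(f) diff(range(g(f))) == 0, logical(1))) &&
    all(vapply(reports, function(r)
      identical(r$c_ci, reports[[1]]$c_ci) &&
        identical(r$eo_ci, reports[[1]]$eo_ci), logical(1)))
  if (identical_reports) return(reports[[1]])
  # C on logit working scale; delta method: var(logit c) = var(c)/(c(1-c))^2
  cs <- pmin(pmax(g("c"), 1e-8), 1 - 1e-8)
  logit_var <- g("c_var") / (cs * (1 - cs))^2
  pc <- rubin_pool(logit(cs), logit_var)
  tq <- if (is.finite(pc$df)) stats::qt(0.975, pc$df) else 1.96
  c_ci <- expit(pc$q_bar + c(-1, 1) * tq * sqrt(pc$t))
  c_point <- mean(g("c"))
  c_ci <- c(min(c_ci[1], c_point), max(c_ci[2], c_point))
  # E/O on log working scale; Poisson variance 1/O
  ratios <- g("eo_ratio")
  pe <- rubin_pool(log(ratios), 1 / g("o"))
  tq2 <- if (is.finite(pe$df)) stats::qt(0.975, pe$df) else 1.96
  eo_ci <- exp(pe$q_bar + c(-1, 1) * tq2 * sqrt(pe$t))
  eo_point <- mean(ratios)
  eo_ci <- c(min(eo_ci[1], eo_point), max(eo_ci[2], eo_point))
  methods <- unique(vapply(reports, `[[`, character(1), "method"))
  states <- unique(vapply(reports, `[[`, character(1), "state"))
  structure(
    list(model = models,
         method = if (length(methods) == 1) methods else "mice",
         state = if (length(states) == 1) states else "original",
         e = mean(g("e")), o = mean(g("o")),
         eo_ratio = eo_point, eo_ci = eo_ci,
         brier = mean(g("brier")), yates_slope = mean(g("yates_slope")),
         c = c_point, c_ci = c_ci,
         c_var = pc$t * (c_point * (1 - c_point))^2,
         n_eff = round(mean(g("n_eff")))),
    class = "performance_report"
  )
}
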