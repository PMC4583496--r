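#' Configure a benchmark run
#'
#' @param table an existing `cohort_table` (overrides the generator).
#' @param generator a `generator_config` used when no table is supplied.
#' @param missingness a `missingness_config` applied after generation.
#' @param methods subset of `c("deletion", "simple", "conditional",
#'   "stochastic", "mice")`.
#' @param models named list of `risk_model_spec` objects.
#' @param m,iterations multiple-imputation settings.
#' @param seed master seed; every stage derives its own sub-seed from it,
#'   so adding a method never perturbs another method's draws.
#' @param exclusion_flag optional binary variable name; flagged rows are
#'   excluded before any analysis.
#' @return object of class `run_config`.
#' @export
run_config <- function(table = NULL, generator = NULL, missingness = NULL,
                       methods = c("deletion", "simple", "conditional",
                                   "stochastic", "mice"),
                       models = builtin_registry(),
                       m = 5, iterations = 10, seed = 1,
                       exclusion_flag = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (!length(models)) stop("at least one model is required", call. = FALSE)
  if (is.null(table) && is.null(generator))
    stop("supply a cohort table or a generator config", call. = FALSE)
  structure(
    list(table = table, generator = generator, missingness = missingness,
         methods = methods, models = models, m = m,
         iterations = iterations, seed = seed,
         exclusion_flag = exclusion_flag),
    class = "run_config"
  )
}

report_row <- function(r) {
  data.frame(model = r$model, method = r$method, state = r$state,
             EO = r$eo_ratio, EO_lo = r$eo_ci[1], EO_hi = r$eo_ci[2],
             brier = r$brier, yates = r$yates_slope,
             C = r$c, C_lo = r$c_ci[1], C_hi = r$c_ci[2],
             n_eff = r$n_eff, error = NA_character_)
}

error_row <- function(model, method, state, msg) {
  data.frame(model = model, method = method, state = state,
             EO = NA_real_, EO_lo = NA_real_, EO_hi = NA_real_,
             brier = NA_real_, yates = NA_real_,
             C = NA_real_, C_lo = NA_real_, C_hi = NA_real_,
             n_eff = NA_integer_, error = msg)
}

# Evaluate one model on one completed dataset: original state, then
# intercept recalibration, then adjusted state. Errors become NA rows
# carrying the reason, never a crash of the whole run.
evaluate_cell <- function(model, ds, method_label) {
  tab <- ds$table
  y <- tab$data[[tab$outcome_name]]
  orig <- tryCatch({
    pr <- predict_risk(model, tab)
    evaluate_performance(pr, y, "original", model$name, method_label)
  }, error = function(e) conditionMessage(e))
  adj <- tryCatch({
    recal <- recalibrate_intercept(model, tab)
    pr2 <- predict_risk(recal, tab)
    evaluate_performance(pr2, y, "adjusted", model$name, method_label)
  }, error = function(e) conditionMessage(e))
  list(original = orig, adjusted = adj)
}

#' Run the full imputation-method comparison
#'
#' Executes the benchmark: (optional) exclusion of previously diagnosed
#' participants, missingness summary, each requested imputation method,
#' scoring of every model on every completed dataset, performance
#' evaluation before recalibration, per-dataset intercept recalibration,
#' and evaluation after recalibration. For multiple imputation, every
#' metric panel is computed on each of the m completed datasets separately
#' and then pooled by Rubin's rules; the per-dataset sub-table is retained.
#' The run is deterministic under a fixed seed; cells that fail (e.g. a
#' single-class outcome after deletion on a tiny cohort) are recorded as NA
#' with a reason and the run continues.
#'
#' @param config a [run_config()].
#' @return object of class `method_comparison`: list with `table` (long
#'   data.frame of all cells), `reports` (the `performance_report`
#'   objects), `mi_subtable` (per-MI-dataset long data.frame),
#'   `missingness` (the pre-imputation summary), `characteristics`
#'   (per-method variable summaries) and `manifest`.
#' @export
run_comparison <- function(config) {
  stopifnot(inherits(config, "run_config"))
  excluded <- 0L
  if (!is.null(config$table)) {
    cohort <- config$table
  } else {
    cohort <- generate_complete_cohort(
      config$generator, seed = derive_seed(config$seed, "generate"))
    if (!is.null(config$missingness))
      cohort <- apply_missingness(cohort, config$missingness,
                                  seed = derive_seed(config$seed, "ampute"))
  }
  if (!is.null(config$exclusion_flag)) {
    ex <- exclude_previously_diagnosed(cohort, config$exclusion_flag)
    cohort <- ex$table
    excluded <- ex$excluded_count
  }
  msummary <- summarize_missingness(cohort)

  rows <- list(); reports <- list(); mi_rows <- list()
  char_tabs <- list(original = characteristics_table(cohort))
  fallback_log <- character(); checksums <- character()

  for (method in config$methods) {
    imp <- impute_method(cohort, method, m = config$m,
                         iterations = config$iterations,
                         seed = derive_seed(config$seed, method))
    if (inherits(imp, "multiple_imputation_result")) {
      dlogs <- unlist(lapply(imp$datasets, `[[`, "log"))
      if (length(dlogs)) fallback_log <- c(fallback_log, unique(dlogs))
      char_tabs[[method]] <- characteristics_table(imp$datasets[[1]]$table)
      checksums[method] <- object_checksum(
        lapply(imp$datasets, function(d) d$table$data))
      for (model in config$models) {
        per_orig <- list(); per_adj <- list(); errs <- character()
        for (k in seq_len(imp$m)) {
          cell <- evaluate_cell(model, imp$datasets[[k]], method)
          if (inherits(cell$original, "performance_report")) {
            per_orig[[length(per_orig) + 1]] <- cell$original
            mi_rows[[length(mi_rows) + 1]] <-
              cbind(dataset = k, report_row(cell$original))
          } else errs <- c(errs, cell$original)
          if (inherits(cell$adjusted, "performance_report")) {
            per_adj[[length(per_adj) + 1]] <- cell$adjusted
            mi_rows[[length(mi_rows) + 1]] <-
              cbind(dataset = k, report_row(cell$adjusted))
          } else errs <- c(errs, cell$adjusted)
        }
        for (state in c("original", "adjusted")) {
          per <- if (state == "original") per_orig else per_adj
          if (length(per) >= 2) {
            pooled <- pool_reports(per, m = imp$m)
            pooled$state <- state
            reports[[length(reports) + 1]] <- pooled
            rows[[length(rows) + 1]] <- report_row(pooled)
          } else {
            rows[[length(rows) + 1]] <- error_row(
              model$name, method, state,
              paste(unique(errs), collapse = "; "))
          }
        }
      }
    } else {
      if (length(imp$log)) fallback_log <- c(fallback_log, imp$log)
      char_tabs[[method]] <- characteristics_table(imp$table)
      checksums[method] <- object_checksum(imp$table$data)
      for (model in config$models) {
        cell <- evaluate_cell(model, imp, method)
        for (state in c("original", "adjusted")) {
          r <- cell[[state]]
          if (inherits(r, "performance_report")) {
            reports[[length(reports) + 1]] <- r
            rows[[length(rows) + 1]] <- report_row(r)
          } else {
            rows[[length(rows) + 1]] <-
              error_row(model$name, method, state, r)
          }
        }
      }
    }
  }

  manifest <- list(
    methods = config$methods,
    models = vapply(config$models, `[[`, character(1), "name"),
    m = config$m, iterations = config$iterations, seed = config$seed,
    n = n_participants(cohort), excluded_count = excluded,
    n_any_missing = attr(msummary, "n_any_missing"),
    fallback_log = fallback_log,
    dataset_checksums = checksums,
    package_version = as.character(utils::packageVersion("missbench")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  structure(
    list(table = do.call(rbind, rows),
         reports = reports,
         mi_subtable = if (length(mi_rows)) do.call(rbind, mi_rows) else NULL,
         missingness = msummary,
         characteristics = char_tabs,
         cohort = cohort,
         manifest = manifest),
    class = "method_comparison"
  )
}

#' @export
print.method_comparison <- function(x, digits = 3, ...) {
  cat("<method_comparison> ", length(unique(x$table$model)), " models x ",
      length(unique(x$table$method)), " methods x 2 calibration states (n = ",
      x$manifest$n, ")\n\n", sep = "")
  df <- x$table
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.method_comparison <- function(object, ...) {
  print(object$missingness)
  cat("\n")
  print(object)
  invisible(object$table)
}

#' @export
as.data.frame.method_comparison <- function(x, ...) x$table

# Per-method variable characteristics: mean (SD) for continuous, level
# counts for binary/categorical — the per-method summary a benchmark
# reports alongside the metric grid.
characteristics_table <- function(table) {
  rows <- lapply(table$schema, function(v) {
    x <- table$data[[v$name]]
    if (v$kind == "continuous") {
      data.frame(variable = v$name,
                 summary = sprintf("%.1f (%.1f)", mean(x, na.rm = TRUE),
                                   stats::sd(x, na.rm = TRUE)),
                 n_observed = sum(!is.na(x)))
    } else {
      lv <- if (v$kind == "binary") c("1", "0") else v$categories
      counts <- table(factor(as.character(x), levels = lv))
      data.frame(variable = v$name,
                 summary = paste(counts, collapse = "/"),
                 n_observed = sum(!is.na(x)))
    }
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Render a comparison to files
#'
#' Writes the benchmark grid in a wide layout (rows = model x performance
#' measure, one column pair per method, mirroring the usual
#' methods-comparison table), a tidy long-format CSV, per-method
#' characteristics tables, and the per-MI-dataset sub-table.
#'
#' @param comparison a `method_comparison`.
#' @param dir output directory (created if needed).
#' @param format one of `"csv"`, `"json"`, `"markdown"`.
#' @return character vector of written file paths, invisibly.
#' @export
render_report <- function(comparison, dir, format = c("csv", "json",
                                                      "markdown")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- comparison$table
  written <- character()
  fmt_cell <- function(r) {
    if (is.na(r$EO)) return(c(EO = NA, Brier = NA, Yates = NA, C = NA))
    c(EO = sprintf("%.2f (%.2f-%.2f)", r$EO, r$EO_lo, r$EO_hi),
      Brier = sprintf("%.3f", r$brier),
      Yates = sprintf("%.3f", r$yates),
      C = sprintf("%.2f (%.2f-%.2f)", r$C, r$C_lo, r$C_hi))
  }
  wide <- list()
  for (mod in unique(df$model)) {
    for (meas in c("EO", "Brier", "Yates", "C")) {
      row <- list(model = mod, measure = meas)
      for (meth in unique(df$method)) {
        for (st in c("original", "adjusted")) {
          r <- df[df$model == mod & df$method == meth & df$state == st, ]
          row[[paste(meth, st, sep = "_")]] <-
            if (nrow(r)) unname(fmt_cell(r[1, ])[meas]) else NA
        }
      }
      wide[[length(wide) + 1]] <- as.data.frame(row)
    }
  }
  wide <- do.call(rbind, wide)
  if (format == "csv") {
    p1 <- file.path(dir, "comparison_wide.csv")
    p2 <- file.path(dir, "comparison_long.csv")
    utils::write.csv(wide, p1, row.names = FALSE)
    utils::write.csv(df, p2, row.names = FALSE)
    written <- c(p1, p2)
    if (!is.null(comparison$mi_subtable)) {
      p3 <- file.path(dir, "mi_datasets.csv")
      utils::write.csv(comparison$mi_subtable, p3, row.names = FALSE)
      written <- c(written, p3)
    }
    for (nm in names(comparison$characteristics)) {
      p <- file.path(dir, sprintf("characteristics_%s.csv", nm))
      utils::write.csv(comparison$characteristics[[nm]], p,
                       row.names = FALSE)
      written <- c(written, p)
    }
  } else if (format == "json") {
    p <- file.path(dir, "comparison.json")
    jsonlite::write_json(
      list(long = df, wide = wide, manifest = comparison$manifest),
      p, auto_unbox = TRUE, digits = NA, na = "null")
    written <- p
  } else {
    p <- file.path(dir, "comparison.md")
    con <- file(p, "w")
    hdr <- names(wide)
    writeLines(paste0("| ", paste(hdr, collapse = " | "), " |"), con)
    writeLines(paste0("|", paste(rep("---", length(hdr)), collapse = "|"),
                      "|"), con)
    for (i in seq_len(nrow(wide)))
      writeLines(paste0("| ", paste(unlist(wide[i, ]), collapse = " | "),
                        " |"), con)
    close(con)
    written <- p
  }
  invisible(written)
}
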