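#' Declare a cohort variable
#'
#' A variable specification records the name, measurement kind and (for
#' categorical variables) the ordered category labels of one cohort column.
#' Binary variables are stored as 0/1 integers; an optional label map records
#' what 1 means (e.g. `female = 1`).
#'
#' @param name variable identifier (must be a valid column name).
#' @param kind one of `"continuous"`, `"binary"`, `"categorical"`.
#' @param categories ordered character vector of category labels
#'   (categorical only; at least two distinct labels).
#' @param units free-text measurement units (e.g. `"years"`, `"kg/m2"`).
#' @param labels optional named 0/1 map documenting the binary coding.
#' @return an object of class `variable_spec`.
#' @export
variable_spec <- function(name, kind, categories = NULL, units = "",
                          labels = NULL) {
  kind <- match.arg(kind, c("continuous", "binary", "categorical"))
  if (kind == "categorical") {
    if (is.null(categories) || length(unique(categories)) < 2)
      stop("categorical variable '", name,
           "' needs at least 2 distinct category labels", call. = FALSE)
    categories <- as.character(categories)
  } else {
    categories <- NULL
  }
  structure(
    list(name = as.character(name), kind = kind, categories = categories,
         units = units, labels = labels),
    class = "variable_spec"
  )
}

#' Assemble a cohort schema
#'
#' @param ... `variable_spec` objects (or a single list of them).
#' @return an object of class `cohort_schema`: a named list of variable specs.
#' @export
cohort_schema <- function(...) {
  specs <- list(...)
  if (length(specs) == 1 && !inherits(specs[[1]], "variable_spec"))
    specs <- specs[[1]]
  ok <- vapply(specs, inherits, logical(1), "variable_spec")
  if (!all(ok)) stop("all arguments must be variable_spec objects", call. = FALSE)
  nms <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate variable names in schema", call. = FALSE)
  names(specs) <- nms
  structure(specs, class = "cohort_schema")
}

#' @export
print.cohort_schema <- function(x, ...) {
  cat("<cohort_schema> ", length(x), " variables\n", sep = "")
  for (v in x) {
    extra <- if (v$kind == "categorical")
      paste0(" {", paste(v$categories, collapse = "/"), "}") else ""
    cat(sprintf("  %-22s %-12s%s %s\n", v$name, v$kind, extra, v$units))
  }
  invisible(x)
}

schema_names <- function(schema) vapply(schema, `[[`, character(1), "name")

schema_kinds <- function(schema) {
  k <- vapply(schema, `[[`, character(1), "kind")
  names(k) <- schema_names(schema)
  k
}

#' Read or write a cohort schema as YAML
#'
#' Schema files list one entry per variable with fields `name`, `kind`
#' and, for categorical variables, the ordered `categories`.
#'
#' @param path schema file path.
#' @return `load_schema` returns a `cohort_schema`; `save_schema` returns
#'   `path` invisibly.
#' @export
load_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path, call. = FALSE)
  entries <- yaml::read_yaml(path)
  specs <- lapply(entries, function(e) {
    variable_spec(e$name, e$kind, categories = unlist(e$categories),
                  units = e$units %||% "",
                  labels = unlist(e$labels))
  })
  cohort_schema(specs)
}

#' @rdname load_schema
#' @param schema a `cohort_schema`.
#' @export
save_schema <- function(schema, path) {
  entries <- lapply(unclass(schema), function(v) {
    out <- list(name = v$name, kind = v$kind)
    if (!is.null(v$categories)) out$categories <- as.list(v$categories)
    if (nzchar(v$units)) out$units <- v$units
    if (!is.null(v$labels)) out$labels <- as.list(v$labels)
    out
  })
  yaml::write_yaml(unname(entries), path)
  invisible(path)
}

#' Default schema for the Bellville-South-style cohort
#'
#' Fourteen analysis variables (age, gender, body-mass index, waist
#' circumference, systolic and diastolic blood pressure, four family-history
#' indicators, corticosteroid use, antihypertensive medication, three-level
#' smoking status and the prevalent-undiagnosed-diabetes outcome) plus the
#' previously-diagnosed-diabetes exclusion flag.
#'
#' @return a `cohort_schema`.
#' @export
bellville_schema <- function() {
  cohort_schema(
    variable_spec("age", "continuous", units = "years"),
    variable_spec("gender", "binary", labels = c(female = 1), units = ""),
    variable_spec("bmi", "continuous", units = "kg/m2"),
    variable_spec("waist_circumference", "continuous", units = "cm"),
    variable_spec("sbp", "continuous", units = "mmHg"),
    variable_spec("dbp", "continuous", units = "mmHg"),
    variable_spec("fh_mother", "binary"),
    variable_spec("fh_father", "binary"),
    variable_spec("fh_sister", "binary"),
    variable_spec("fh_brother", "binary"),
    variable_spec("corticosteroids", "binary"),
    variable_spec("htn_medication", "binary"),
    variable_spec("smoking", "categorical",
                  categories = c("current", "past", "no")),
    variable_spec("undiagnosed_diabetes", "binary"),
    variable_spec("known_diabetes", "binary")
  )
}
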