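#' Construct a cohort table
#'
#' A cohort table couples a rectangular participant-by-variable data frame
#' with a `cohort_schema` and the name of the binary outcome variable.
#' Missing cells are `NA`; continuous variables are numeric, binary variables
#' 0/1 integers, categorical variables characters drawn from the schema's
#' category labels. Row order is preserved by every operation in the package.
#'
#' @param data data.frame with one column per schema variable.
#' @param schema a `cohort_schema`.
#' @param outcome_name name of the binary outcome variable.
#' @return an object of class `cohort_table`.
#' @export
cohort_table <- function(data, schema, outcome_name) {
  stopifnot(inherits(schema, "cohort_schema"))
  nms <- schema_names(schema)
  missing_cols <- setdiff(nms, names(data))
  if (length(missing_cols))
    stop("data lacks schema column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!outcome_name %in% nms)
    stop("outcome '", outcome_name, "' not in schema", call. = FALSE)
  if (schema[[outcome_name]]$kind != "binary")
    stop("outcome '", outcome_name, "' must be binary", call. = FALSE)
  data <- as.data.frame(data)[, nms, drop = FALSE]
  for (v in schema) {
    col <- data[[v$name]]
    data[[v$name]] <- switch(v$kind,
      continuous = as.numeric(col),
      binary = {
        x <- as.integer(col)
        bad <- !is.na(x) & !(x %in% c(0L, 1L))
        if (any(bad))
          stop("binary variable '", v$name, "' has values outside {0,1} (row ",
               which(bad)[1], ")", call. = FALSE)
        x
      },
      categorical = {
        x <- as.character(col)
        bad <- !is.na(x) & !(x %in% v$categories)
        if (any(bad))
          stop("categorical variable '", v$name, "' has unknown label '",
               x[bad][1], "' (row ", which(bad)[1], ")", call. = FALSE)
        x
      })
  }
  rownames(data) <- NULL
  structure(
    list(data = data, schema = schema, outcome_name = outcome_name),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> ", nrow(x$data), " participants x ",
      ncol(x$data), " variables; outcome: ", x$outcome_name, "\n", sep = "")
  nmiss <- sum(is.na(x$data))
  cat("  missing cells: ", nmiss, " (",
      round(100 * nmiss / max(1, prod(dim(x$data))), 1), "% of cells)\n",
      sep = "")
  invisible(x)
}

#' @export
summary.cohort_table <- function(object, ...) {
  s <- summarize_missingness(object)
  print(object)
  print(s)
  invisible(s)
}

#' Number of participants in a cohort table
#' @param table a `cohort_table`.
#' @return integer row count.
#' @export
n_participants <- function(table) nrow(table$data)

#' Missingness mask of a cohort table
#' @param table a `cohort_table`.
#' @return logical matrix, `TRUE` where the cell is missing.
#' @export
missing_mask <- function(table) {
  m <- is.na(as.matrix(table$data))
  dimnames(m) <- list(NULL, names(table$data))
  m
}

#' Read a cohort from delimited text
#'
#' Reads a CSV file (one header row, UTF-8, "." decimal separator) against a
#' declared schema. Cells that are empty or equal to one of `missing_tokens`
#' become missing. Values are parsed according to each variable's declared
#' kind, and a parse failure is reported with the offending row and column.
#'
#' @param path file path.
#' @param schema a `cohort_schema`; the file's header must contain every
#'   schema variable (extra columns are ignored).
#' @param outcome_name binary outcome variable name.
#' @param missing_tokens character vector of tokens read as missing
#'   (the empty string is always treated as missing).
#' @return a `cohort_table`.
#' @export
read_cohort <- function(path, schema, outcome_name = "undiagnosed_diabetes",
                        missing_tokens = c("", "NA")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  nms <- schema_names(schema)
  absent <- setdiff(nms, names(raw))
  if (length(absent))
    stop("file lacks required column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  out <- raw[, nms, drop = FALSE]
  tokens <- union(missing_tokens, "")
  for (v in schema) {
    x <- out[[v$name]]
    x[x %in% tokens] <- NA_character_
    if (v$kind %in% c("continuous", "binary")) {
      parsed <- suppressWarnings(as.numeric(x))
      bad <- which(!is.na(x) & is.na(parsed))
      if (length(bad))
        stop("cannot parse '", x[bad[1]], "' as ", v$kind, " (row ", bad[1],
             ", column ", v$name, ")", call. = FALSE)
      out[[v$name]] <- parsed
    } else {
      bad <- which(!is.na(x) & !(x %in% v$categories))
      if (length(bad))
        stop("unknown category '", x[bad[1]], "' (row ", bad[1], ", column ",
             v$name, ")", call. = FALSE)
      out[[v$name]] <- x
    }
  }
  cohort_table(out, schema, outcome_name)
}

#' Write a cohort to delimited text
#'
#' Missing cells are written as `missing_token` (empty string by default),
#' so `read_cohort(write_cohort(x))` reproduces values and mask exactly.
#'
#' @param table a `cohort_table`.
#' @param path destination file path.
#' @param missing_token token used for missing cells.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path, missing_token = "") {
  df <- table$data
  out <- lapply(names(df), function(nm) {
    x <- as.character(df[[nm]])
    x[is.na(x)] <- missing_token
    x
  })
  names(out) <- names(df)
  utils::write.csv(as.data.frame(out, check.names = FALSE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Exclude previously diagnosed participants
#'
#' Drops the rows whose exclusion flag equals 1 and reports how many were
#' removed, mirroring the screening-study convention of restricting external
#' validation to participants without a prior diagnosis.
#'
#' @param table a `cohort_table`.
#' @param flag_name name of the binary exclusion-flag variable.
#' @return list with `table` (the restricted cohort, flag column retained)
#'   and `excluded_count`.
#' @export
exclude_previously_diagnosed <- function(table, flag_name = "known_diabetes") {
  if (!flag_name %in% names(table$data))
    stop("flag variable '", flag_name, "' not in cohort", call. = FALSE)
  flag <- table$data[[flag_name]]
  keep <- is.na(flag) | flag != 1L
  out <- table
  out$data <- table$data[keep, , drop = FALSE]
  rownames(out$data) <- NULL
  list(table = out, excluded_count = sum(!keep))
}

#' Summarise per-variable missingness
#'
#' @param table a `cohort_table` with at least one row.
#' @return object of class `missingness_summary`: a data.frame with one row
#'   per variable (`variable`, `missing_count`, `missing_percent`) plus
#'   attributes `n` and `n_any_missing`.
#' @export
summarize_missingness <- function(table) {
  n <- n_participants(table)
  if (n < 1) stop("cohort table is empty", call. = FALSE)
  mask <- missing_mask(table)
  counts <- colSums(mask)
  out <- data.frame(
    variable = names(counts),
    missing_count = as.integer(counts),
    missing_percent = 100 * counts / n,
    row.names = NULL
  )
  structure(out, n = n, n_any_missing = sum(rowSums(mask) > 0),
            class = c("missingness_summary", "data.frame"))
}

#' @export
print.missingness_summary <- function(x, ...) {
  n <- attr(x, "n")
  k <- attr(x, "n_any_missing")
  cat("Missingness over ", n, " participants: ", k, " (",
      round(100 * k / n, 1), "%) with >=1 missing value\n", sep = "")
  df <- as.data.frame(x)
  df$missing_percent <- round(df$missing_percent, 1)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Enumerate missingness patterns
#'
#' Aggregates the rows by their exact missingness mask, from the most to the
#' least frequent pattern (a tabular analogue of an aggregation plot).
#'
#' @param table a `cohort_table` with at least one row.
#' @return data.frame with one logical column per variable (`TRUE` =
#'   missing) plus a `frequency` column; frequencies sum to the row count.
#' @export
enumerate_patterns <- function(table) {
  if (n_participants(table) < 1) stop("cohort table is empty", call. = FALSE)
  mask <- missing_mask(table)
  key <- apply(mask, 1, paste, collapse = ",")
  tab <- table(key)
  ord <- order(-as.integer(tab), names(tab))
  keys <- names(tab)[ord]
  pat <- t(vapply(strsplit(keys, ","), function(s) as.logical(s),
                  logical(ncol(mask))))
  out <- as.data.frame(pat)
  names(out) <- colnames(mask)
  out$frequency <- as.integer(tab)[ord]
  out
}
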