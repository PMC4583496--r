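#' Inverse logit with overflow protection
#'
#' Maps a linear predictor to a probability. The linear predictor is clamped
#' to +/- 35 before exponentiation so that the returned probability is always
#' strictly inside (0, 1) in double precision.
#'
#' @param lp numeric vector of linear-predictor values.
#' @return numeric vector of probabilities in (0, 1).
#' @export
expit <- function(lp) {
  lp <- pmin(pmax(lp, -35), 35)
  1 / (1 + exp(-lp))
}

#' Logit transform
#' @param p probabilities strictly in (0, 1).
#' @return numeric vector of log-odds.
#' @export
logit <- function(p) log(p / (1 - p))

# Deterministic sub-seed from a master seed and a string label (+ index).
# Keeps independent stages decoupled: adding a method never perturbs the
# random draws of another. Result is a valid 32-bit seed.
derive_seed <- function(master, label, index = 0L) {
  codes <- utf8ToInt(as.character(label))
  h <- as.double(master) %% 2147483647
  for (cd in codes) h <- (h * 131 + cd) %% 2147483647
  h <- (h * 131 + as.double(index) + 1) %% 2147483647
  as.integer(h)
}

# Evaluate an expression under a local RNG state (seed may be NULL = leave
# the global stream untouched).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Observed mode of a vector; ties broken by `levels` order (first wins).
observed_mode <- function(x, levels_order) {
  x <- x[!is.na(x)]
  tab <- table(factor(x, levels = levels_order))
  names(tab)[which.max(tab)]
}

# md5 of a deterministic text rendering of an R object (text files only in
# the deliverable, so checksums are computed over dput output, not serialize).
object_checksum <- function(x) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf), add = TRUE)
  writeLines(deparse(x), tf)
  unname(tools::md5sum(tf))
}
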