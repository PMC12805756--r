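# Shared internal helpers.

.norm2 <- function(x) sqrt(sum(x * x))

.row_norms <- function(m) sqrt(rowSums(m * m))

.as_state_matrix <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 2L) stop("state matrices must have two columns", call. = FALSE)
    storage.mode(x) <- "double"
    return(x)
  }
  if (length(x) != 2L) stop("a state must be a length-2 numeric vector", call. = FALSE)
  matrix(as.numeric(x), ncol = 2L)
}

.check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE,
                          integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop(sprintf("'%s' = %g is outside the admissible range %s%g, %g%s", name, x,
                 if (strict_lower) "(" else "[", lower, upper,
                 if (strict_upper) ")" else "]"), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  invisible(x)
}

.check_vec2 <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || !all(is.finite(x)))
    stop(sprintf("'%s' must be a finite length-2 numeric vector", name), call. = FALSE)
  as.numeric(x)
}

# TSV writer with shortest round-trip representation so reruns are
# byte-comparable and read-backs are exact.
.write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Total variation distance between two discrete distributions
#'
#' Both arguments are non-negative weight vectors over the same bins; each is
#' normalised to sum to one before the distance is computed.
#'
#' @param p,q non-negative numeric vectors of equal length.
#' @return A number in \[0, 1\].
#' @export
tv_distance <- function(p, q) {
  if (length(p) != length(q)) stop("'p' and 'q' must have equal length", call. = FALSE)
  if (any(p < 0) || any(q < 0)) stop("weights must be non-negative", call. = FALSE)
  0.5 * sum(abs(p / sum(p) - q / sum(q)))
}
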