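# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number.", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number.", name), call. = FALSE)
  }
  ok <- if (strict) x > lower && x < upper else x >= lower && x <= upper
  if (!ok) {
    stop(sprintf("`%s` = %s is outside the admissible range (%s, %s).",
                 name, format(x), format(lower), format(upper)),
         call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min) {
    stop(sprintf("`%s` must be an integer >= %d.", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

# Spearman correlation as Pearson on mid-ranks; complete observations only.
spearman_cor <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

# Extract a subjects x parcels matrix from a hurst_map or plain matrix.
as_hurst_matrix <- function(x) {
  if (inherits(x, "hurst_map")) return(x$values)
  if (is.matrix(x)) return(x)
  if (is.data.frame(x)) return(as.matrix(x))
  stop("Expected a `hurst_map` or a subjects x parcels matrix.", call. = FALSE)
}

# Extract the numeric score matrix from a factor table (tibble with a subject
# column, or a plain matrix).
as_factor_matrix <- function(y) {
  if (is.matrix(y)) return(y)
  if (is.data.frame(y)) {
    keep <- vapply(y, is.numeric, logical(1)) & names(y) != "subject"
    return(as.matrix(y[, keep, drop = FALSE]))
  }
  stop("Expected a factor-score table (data frame) or matrix.", call. = FALSE)
}
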