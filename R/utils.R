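# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Trapezoidal integral of y over x
#'
#' Single-point and empty inputs integrate to 0.
#' @noRd
trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  o <- order(x)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (head(y, -1L) + y[-1L]) / 2)
}

# Evaluate an expression under a deterministic PRNG stream derived from a base
# seed and an operation tag, restoring the caller's RNG state afterwards. One
# stream per generator operation keeps fixtures stable when operations are
# added.
with_op_seed <- function(seed, tag, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  derived <- (as.numeric(seed) + sum(utf8ToInt(tag)) * 1009) %% 2147483647
  set.seed(as.integer(derived))
  force(expr)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

check_fraction <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_config(field, "must be a single value in [0, 1]")
  invisible(x)
}

check_count <- function(x, field, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop_config(field, sprintf("must be a single integer >= %d", min))
  invisible(as.integer(x))
}

check_range <- function(x, field, min = NULL) {
  if (!is.numeric(x) || length(x) != 2L || any(is.na(x)) || x[2] < x[1])
    stop_config(field, "must be a non-decreasing pair c(lo, hi)")
  if (!is.null(min) && any(x < min))
    stop_config(field, sprintf("values must be >= %s", min))
  invisible(x)
}
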