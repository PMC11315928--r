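#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a message naming the offending field
#' @noRd
stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_field(field, sprintf("must lie in %s%s, %s%s",
                              if (open_lower) "(" else "[", lower, upper,
                              if (open_upper) ")" else "]"))
  invisible(x)
}

#' Deterministic child seeds from one root seed
#'
#' Draws `n` independent 31-bit integer seeds from the root seed so that
#' per-subject random streams do not depend on iteration order.
#' @noRd
child_seeds <- function(root_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(root_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run an expression under a temporary RNG seed, restoring the caller's stream
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
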