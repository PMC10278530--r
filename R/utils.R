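# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's `.Random.seed`, so generators are
#' deterministic without clobbering the session RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

stop2 <- function(...) stop(..., call. = FALSE)

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is_scalar_number(x)) stop2("'", name, "' must be a finite number")
  if (strict_lower && x <= lower)
    stop2("'", name, "' must be > ", lower, " (got ", x, ")")
  if (!strict_lower && x < lower)
    stop2("'", name, "' must be >= ", lower, " (got ", x, ")")
  if (x > upper) stop2("'", name, "' must be <= ", upper, " (got ", x, ")")
  invisible(x)
}

# clamp numeric vector/array into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
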