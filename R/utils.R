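# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. Every stochastic entry point in the package routes
# its randomness through this so that a seed argument fully determines output
# without clobbering the user's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x)
  if (ok) {
    ok <- if (strict) x > lower && x < upper else x >= lower && x <= upper
  }
  if (!ok) {
    stopf("`%s` must be a single finite number in %s%s, %s%s", name,
          if (strict) "(" else "[", lower, upper, if (strict) ")" else "]")
  }
  invisible(x)
}

assert_binary <- function(x, name) {
  if (!all(x %in% c(0, 1))) stopf("`%s` must contain only 0/1 values", name)
  invisible(x)
}
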