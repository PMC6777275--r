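# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream-specific child seed from a base seed; kept below 2^31.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  x <- 0
  for (p in parts) x <- (x * 69069 + as.numeric(p) %% 2147483647) %% 2147483647
  as.integer(x %% 2147483629 + 1)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is_scalar_number(x)) stopf("`%s` must be a single finite number", name)
  if (x < lower || x > upper) {
    stopf("`%s` must be in [%g, %g], got %g", name, lower, upper, x)
  }
  invisible(x)
}

# Trapezoid rule on an ordered grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}
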