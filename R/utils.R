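# Internal helpers: seeded evaluation, sub-stream seeds, validation.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
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
  force(code)
}

# Deterministic sub-stream seed derived from a base seed and a string key.
# Keeps independent generator streams stable when unrelated dimensions of a
# simulation change (e.g. adding genes must not shift earlier genes' draws).
substream_seed <- function(seed, key) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (k in utf8ToInt(key)) h <- (h * 31 + k) %% m
  as.integer(h)
}

stopf <- function(fmt, ..., class = "gcntools_error", call. = FALSE) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "gcntools_error")))
}

assert_number <- function(x, field, lower = -Inf, upper = Inf,
                          integer = FALSE, open_lower = FALSE, open_upper = FALSE) {
  ok <- length(x) == 1 && is.numeric(x) && is.finite(x) &&
    (if (open_lower) x > lower else x >= lower) &&
    (if (open_upper) x < upper else x <= upper) &&
    (!integer || x == round(x))
  if (!ok) {
    stopf("invalid value for '%s': must be a %s in %s%s, %s%s (got %s)",
          field, if (integer) "whole number" else "number",
          if (open_lower) "(" else "[", format(lower),
          format(upper), if (open_upper) ")" else "]",
          paste(format(x), collapse = ", "),
          class = "gcntools_validation_error")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_stage <- function(verbose, fmt, ...) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}
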