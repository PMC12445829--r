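# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar_number <- function(x, field, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  if (x < lower || (strict_lower && x <= lower))
    stop_field(field, sprintf("must be %s %s", if (strict_lower) ">" else ">=", lower))
  if (x > upper || (strict_upper && x >= upper))
    stop_field(field, sprintf("must be %s %s", if (strict_upper) "<" else "<=", upper))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# day-of-year (1 = Jan 1) for Date vectors
doy_of <- function(dates) as.POSIXlt(dates)$yday + 1L
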