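# internal assertion helpers

stop_bad_arg <- function(name, msg) {
  stop(sprintf("invalid `%s`: %s", name, msg), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    stop_bad_arg(name, "must not be NULL")
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_bad_arg(name, "must be a single finite number")
  if (x < lower || x > upper)
    stop_bad_arg(name, sprintf("must be in [%g, %g], got %g", lower, upper, x))
  invisible(x)
}

check_numeric_vec <- function(x, name, lower = -Inf, finite = TRUE) {
  if (!is.numeric(x) || length(x) == 0L)
    stop_bad_arg(name, "must be a non-empty numeric vector")
  if (finite && any(!is.finite(x)))
    stop_bad_arg(name, "must be finite")
  if (any(x < lower))
    stop_bad_arg(name, sprintf("must be >= %g", lower))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
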