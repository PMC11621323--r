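# Internal validation helpers. All user-facing errors carry a subclass under
# "aquafluct_error" so callers can condition on the failure mode.

stop_aq <- function(message, class, ...) {
  abort(message, class = c(paste0("aquafluct_error_", class), "aquafluct_error"), ...)
}

check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || any(!is.finite(x)) || (strict && any(x <= 0)) ||
      (!strict && any(x < 0))) {
    stop_aq(sprintf("`%s` must be %s finite numeric", name,
                    if (strict) "a strictly positive" else "a non-negative"),
            "invalid_parameter")
  }
  invisible(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop_aq(sprintf("`%s` must be a single value in [0, 1]", name),
            "invalid_parameter")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    stop_aq(sprintf("`%s` must be an integer >= %d", name, min),
            "invalid_parameter")
  }
  invisible(as.integer(x))
}

# Evaluate `expr` under an explicit seed without touching the caller's RNG
# state. Seeds are always explicit function arguments in this package.
with_seed_aq <- function(seed, expr) {
  check_count(seed, "seed", min = 0L)
  withr::with_seed(as.integer(seed), expr)
}
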