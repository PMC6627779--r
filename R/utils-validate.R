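# Internal argument checks. All user-facing errors funnel through these so
# messages consistently name the offending field.

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("quenchbind_validation_error", "error")))
}

stop_schema <- function(...) {
  stop(errorCondition(paste0(...), class = c("quenchbind_schema_error", "error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero_lower = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_validation(name, " must be a single finite number")
  }
  if (x < lower || x > upper ||
      (!allow_zero_lower && x == lower)) {
    stop_validation(name, " must be in ",
                    if (allow_zero_lower) "[" else "(",
                    lower, ", ", upper, "]; got ", format(x))
  }
  invisible(x)
}

check_positive <- function(x, name) {
  check_number(x, name, lower = 0, allow_zero_lower = FALSE)
}

check_non_negative <- function(x, name) {
  check_number(x, name, lower = 0)
}

check_numeric_vector <- function(x, name, min_len = 1L, non_negative = FALSE,
                                 positive = FALSE) {
  if (!is.numeric(x) || length(x) < min_len || any(!is.finite(x))) {
    stop_validation(name, " must be a finite numeric vector of length >= ",
                    min_len)
  }
  if (positive && any(x <= 0)) stop_validation(name, " must be strictly positive")
  if (non_negative && any(x < 0)) stop_validation(name, " must be non-negative")
  invisible(x)
}

# Relative spread guard for near-equality tests on concentrations
is_strictly_increasing <- function(x) all(diff(x) > 0)
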