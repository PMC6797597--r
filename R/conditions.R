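# Internal condition helpers. Validation errors (bad user input, malformed
# files, incompatible configs) carry class "snn6ma_validation_error" so the
# command-line layer can map them to exit status 2; everything else is a
# plain runtime error (status 1).

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("snn6ma_validation_error", "snn6ma_error", "error")))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == as.integer(x)
}

check_count <- function(x, name, min = 1) {
  if (!(is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x) && x >= min)) {
    stop_validation(sprintf("'%s' must be a single integer >= %s (got %s)", name, min, deparse(x)))
  }
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (lo_open) x > lo else x >= lo) && (if (hi_open) x < hi else x <= hi)
  if (!ok) stop_validation(sprintf("'%s' must be a number in %s%s, %s%s (got %s)",
    name, if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]", deparse(x)))
  as.numeric(x)
}
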