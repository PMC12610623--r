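# Internal argument checks. All validation errors name the offending field so
# callers (and file readers) can report actionable messages.

.check_number <- function(x, field, positive = FALSE, nonnegative = FALSE,
                          finite = TRUE, len = 1L) {
  if (!is.numeric(x)) {
    stop(sprintf("'%s' must be numeric", field), call. = FALSE)
  }
  if (!is.null(len) && length(x) != len) {
    stop(sprintf("'%s' must have length %d", field, len), call. = FALSE)
  }
  if (finite && any(!is.finite(x))) {
    stop(sprintf("'%s' must be finite", field), call. = FALSE)
  }
  if (positive && any(x <= 0)) {
    stop(sprintf("'%s' must be > 0", field), call. = FALSE)
  }
  if (nonnegative && any(x < 0)) {
    stop(sprintf("'%s' must be >= 0", field), call. = FALSE)
  }
  invisible(x)
}

.check_fraction <- function(x, field) {
  .check_number(x, field)
  if (x < 0 || x > 1) {
    stop(sprintf("'%s' must lie in [0, 1]", field), call. = FALSE)
  }
  invisible(x)
}
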