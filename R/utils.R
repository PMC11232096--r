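`%||%` <- function(a, b) if (is.null(a)) b else a

# scalar field access tolerant of one-row data.frames and lists
assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("%s must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("%s must be > 0", name), call. = FALSE)
  }
  invisible(x)
}
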