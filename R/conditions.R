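# Classed conditions so callers can distinguish validation failures,
# range errors and degenerate inputs programmatically.

ed_stop <- function(class, msg, ..., call = sys.call(-1)) {
  data <- list(...)
  cond <- structure(
    class = c(class, "epidose_error", "error", "condition"),
    c(list(message = msg, call = call), data)
  )
  stop(cond)
}

ed_warn <- function(class, msg, ...) {
  cond <- structure(
    class = c(class, "epidose_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  warning(cond)
}

# scalar numeric check used by constructors
chk_num <- function(x, name, positive = FALSE, nonneg = FALSE, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x)) {
    ed_stop("epidose_validation_error",
            sprintf("'%s' must be a numeric vector of length %d", name, len),
            field = name)
  }
  if (positive && any(x <= 0)) {
    ed_stop("epidose_validation_error",
            sprintf("'%s' must be > 0 (got %s)", name, paste(x, collapse = ", ")),
            field = name)
  }
  if (nonneg && any(x < 0)) {
    ed_stop("epidose_validation_error",
            sprintf("'%s' must be >= 0 (got %s)", name, paste(x, collapse = ", ")),
            field = name)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
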