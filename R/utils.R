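# internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Signal a classed ddidock error
#'
#' All package errors carry class "ddidock_error" plus a specific subclass
#' (e.g. "ddidock_parse_error") so callers can handle them programmatically.
#' @noRd
ddi_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "ddidock_error", "error", "condition")))
}

assert_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    ddi_stop(sprintf("%s must be a single non-empty string", what),
             "ddidock_validation_error")
  }
  invisible(x)
}

# full-precision numeric formatting for text round trips
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}
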