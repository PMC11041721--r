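# Internal helpers shared across modules.

#' Signal a validation error with a machine-readable class
#'
#' @param msg message text.
#' @param class extra condition class prepended to `cm_validation_error`.
#' @noRd
cm_stop <- function(msg, class = NULL) {
  stop(structure(
    class = c(class, "cm_validation_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

cm_warn <- function(msg, class = NULL) {
  warning(structure(
    class = c(class, "cm_validation_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

#' Check that a data.frame carries the required columns
#' @noRd
check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    cm_stop(sprintf(
      "%s is missing required column(s): %s (found: %s)",
      what, paste(missing, collapse = ", "), paste(names(df), collapse = ", ")
    ), class = "cm_schema_error")
  }
  invisible(TRUE)
}

#' Derive a stream-specific seed from a master seed
#'
#' Keeps derived seeds inside the 32-bit integer range.
#' @noRd
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}
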