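# Shared helpers: rounding and argument validation.

#' Round half away from zero
#'
#' All intensity conversions in the package round half-up (0.5 -> 1), unlike
#' base [round()] which rounds half to even. Keeping one rule everywhere makes
#' pixel-level results reproducible across platforms.
#'
#' @param x Numeric vector.
#' @return Numeric vector of rounded values.
#' @keywords internal
round_half_up <- function(x) {
  floor(x + 0.5)
}

stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("colonyquant_validation_error", "colonyquant_error")))
}

stop_format <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("colonyquant_format_error", "colonyquant_error")))
}

stop_fit <- function(fmt, ..., diagnostics = NULL) {
  cond <- errorCondition(sprintf(fmt, ...),
                         class = c("colonyquant_fit_error", "colonyquant_error"))
  cond$diagnostics <- diagnostics
  stop(cond)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
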