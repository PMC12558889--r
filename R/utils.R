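# Classed conditions so callers (and tests) can distinguish failure modes.
stop_equi <- function(subclass, message, ...) {
  rlang::abort(message, class = c(paste0("equipanel_", subclass), "equipanel_error"), ...)
}

stop_domain       <- function(msg, ...) stop_equi("domain_error", msg, ...)
stop_schema       <- function(msg, ...) stop_equi("schema_error", msg, ...)
stop_parse        <- function(msg, ...) stop_equi("parse_error", msg, ...)
stop_validation   <- function(msg, ...) stop_equi("validation_error", msg, ...)
stop_coverage     <- function(msg, ...) stop_equi("coverage_error", msg, ...)
stop_mapping      <- function(msg, ...) stop_equi("mapping_error", msg, ...)
stop_normalization<- function(msg, ...) stop_equi("normalization_error", msg, ...)
stop_feasibility  <- function(msg, ...) stop_equi("feasibility_error", msg, ...)
stop_config       <- function(msg, ...) stop_equi("config_error", msg, ...)
stop_sample_size  <- function(msg, ...) stop_equi("sample_size_error", msg, ...)
stop_design       <- function(msg, ...) stop_equi("design_error", msg, ...)

#' Round half away from zero
#'
#' Printed-style rounding used for report tables: exact halves round up in
#' magnitude (base `round()` rounds halves to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return `x` rounded to `digits` decimals, halves away from zero.
#' @examples
#' round_half_up(c(0.125, 2.5), 2)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}
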