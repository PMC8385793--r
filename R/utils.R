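# Internal helpers: condition classes and rounding.

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("cg_config_error", "cg_error")))
}

stop_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("cg_data_error", "cg_error")))
}

stop_estimation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("cg_estimation_error", "cg_error")))
}

#' Round half away from zero
#'
#' Commercial rounding (0.005 -> 0.01) used when reporting effect sizes to
#' two decimals, as opposed to the banker's rounding of [round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
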