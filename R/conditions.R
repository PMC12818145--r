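# Condition helpers. Two families so callers (and the CLI) can distinguish
# model/schema problems from numerical degeneracy:
#   plsipa_spec_error    -> bad model spec, bad input schema (CLI exit 2)
#   plsipa_numeric_error -> zero variance, rank deficiency, ... (CLI exit 3)

stop_spec <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("plsipa_spec_error", "plsipa_error")))
}

stop_num <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("plsipa_numeric_error", "plsipa_error")))
}

#' Round half away from zero
#'
#' Rounding at display precision for report tables (3 decimals by default).
#' R's [round()] rounds half to even; report tables conventionally round
#' half up, so 0.4645 becomes 0.465.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
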