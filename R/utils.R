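`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Rounding used when matching display conventions of pharmacovigilance
#' tables (2.675 -> 2.68), as opposed to the IEC 60559 ties-to-even rule
#' used by [round()].
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded to `digits` places, ties away from zero.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Format an estimate for display: 2 d.p., en-dash-style "-" for undefined.
fmt_est <- function(x, digits = 2) {
  ifelse(is.na(x), "-", formatC(round_half_up(x, digits), format = "f", digits = digits))
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)
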