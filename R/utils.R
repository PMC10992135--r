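#' Round half away from zero
#'
#' Decimal rounding that breaks ties upward in magnitude (0.275 -> 0.28 at
#' two decimals), matching how the published dose table is printed.
#' \code{base::round()} uses banker's rounding and would disagree on exact
#' half-values.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # nudge by an ulp so values that are exact halves in decimal but stored
  # minutely below them in binary still round up
  trunc(abs(x) * p + 0.5 + 1e-9) / p * sign(x + (x == 0))
}

stop_domain <- function(msg) stop(msg, call. = FALSE)

check_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop_domain(sprintf("`%s` must be finite and non-negative", name))
  }
  invisible(x)
}

check_pos <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop_domain(sprintf("`%s` must be finite and strictly positive", name))
  }
  invisible(x)
}
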