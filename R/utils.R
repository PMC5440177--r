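# Small shared helpers.

#' Round half away from zero
#'
#' Displays agree with the convention used in clinical PET reporting, where
#' ties round away from zero (24.5 -> 25, -0.465 -> -0.47 at two decimals).
#' `base::round()` rounds ties to even, which disagrees at exactly these
#' boundary cases.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(24.5, 0)   # 25
#' round_half_up(-0.465, 2) # -0.47
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || (strict_lower && x <= lower) || x > upper) {
    abort(sprintf("`%s` = %g is outside its valid range.", name, x))
  }
  invisible(x)
}

# trapezoidal cumulative integral, same length as x
cumtrapz1 <- function(t, y) {
  n <- length(t)
  c(0, cumsum(diff(t) * (y[-n] + y[-1]) / 2))
}

trapz1 <- function(t, y) {
  n <- length(t)
  sum(diff(t) * (y[-n] + y[-1]) / 2)
}
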