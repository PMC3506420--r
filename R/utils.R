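#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used in printed regulatory tables.
#' Base R's `round()` rounds half to even, which disagrees with printed
#' values such as 87.45 -> 87.5.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
#' @examples
#' round_half_up(87.45, 1)  # 87.5, where round() gives 87.4
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # tiny relative nudge so values that are exactly .5 after decimal scaling
  # are not lost to binary representation error
  trunc(abs(x) * scale + 0.5 + 1e-9) * sign(x) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_swrisk <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "swrisk_error")))
}
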