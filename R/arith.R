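#' Round half up
#'
#' Taxonomic descriptions print values rounded half-up (2.45 -> 2.5), not with
#' the IEEE round-half-to-even rule used by [base::round()]. Rounding is a
#' presentation step only; stored values are never rounded.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half up.
#' @export
#' @examples
#' round_half_up(2.45, 1)  # 2.5
#' round(2.45, 1)          # 2.4 (banker's rounding)
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  p <- 10^digits
  r <- x * p
  # guard against representation error just below .5 (e.g. 28.499999999996)
  f <- floor(r)
  frac <- r - f
  up <- frac >= 0.5 - 1e-9
  out <- (f + ifelse(up, 1, 0)) / p
  out[is.na(x)] <- NA_real_
  out
}

#' Part size as a percentage of body length
#'
#' Computes `100 * part / body_length`, rounded half-up to `decimals`, the
#' convention used for "% of body length" quantities in digenean descriptions
#' (e.g. a 1045.8 µm cirrus-sac in a 3669.4 µm worm occupies 28.5%).
#'
#' @param part Part length (µm), `>= 0`. Vectorized.
#' @param body_length Body length (µm), `> 0`. Vectorized.
#' @param decimals Decimal places for the printed percentage.
#' @return Numeric vector of percentages.
#' @export
#' @examples
#' percent_of_body(1045.8, 3669.4, 1)  # 28.5
percent_of_body <- function(part, body_length, decimals = 1) {
  if (any(!is.na(body_length) & body_length <= 0)) {
    abort("`body_length` must be > 0.")
  }
  if (any(!is.na(part) & part < 0)) {
    abort("`part` must be >= 0.")
  }
  round_half_up(100 * part / body_length, decimals)
}

#' Ratio with the denominator normalized to one
#'
#' Descriptions quote dimension ratios as "x:1" (e.g. a length to width ratio
#' of 7.9:1). Returns `numerator / denominator` rounded half-up.
#'
#' @param numerator,denominator Lengths in the same unit; `denominator > 0`.
#' @param decimals Decimal places.
#' @return Numeric vector.
#' @export
#' @examples
#' ratio_to_one(4563, 377.1, 1)  # 12.1
ratio_to_one <- function(numerator, denominator, decimals = 1) {
  if (any(!is.na(denominator) & denominator <= 0)) {
    abort("`denominator` must be > 0.")
  }
  round_half_up(numerator / denominator, decimals)
}
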