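#' Round half away from zero
#'
#' Display rounding used throughout the package for percentages and
#' millimetre values. Unlike [base::round()] (banker's rounding), ties are
#' rounded away from zero, which is the convention clinical papers use when
#' printing integer percentages.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep (default 0).
#' @return Numeric vector rounded to `digits` decimals, ties away from zero.
#' @examples
#' round_half_away(0.5)   # 1
#' round_half_away(84.78) # 85
#' round_half_away(-2.5)  # -3
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Integer tenths of a millimetre. All grid-sensitive arithmetic goes through
# this so that values on the 0.1-mm measurement grid behave exactly.
as_tenths <- function(x) as.integer(round(x * 10))

# Snap to the 0.1-mm grid (used on CSV ingest).
snap_tenth <- function(x) as_tenths(x) / 10

# TRUE where x sits on the 0.1-mm grid (one decimal place at most).
on_tenth_grid <- function(x, tol = 1e-6) {
  !is.na(x) & abs(x * 10 - round(x * 10)) < tol
}

`%||%` <- function(a, b) if (is.null(a)) b else a
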