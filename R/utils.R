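#' Round half away from zero
#'
#' Deterministic decimal rounding where ties at 5 in the first dropped digit
#' always round up, matching the convention of published forensic tables.
#' (Base `round()` rounds half to even, which would disagree on exact ties.)
#'
#' @param x numeric vector (assumed nonnegative).
#' @param digits number of decimal places to keep.
#' @return `x` rounded to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 4) {
  floor(x * 10^digits + 0.5) / 10^digits
}

# stop() with a consistent prefix and no call
abort <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# fixed-width frequency formatting used by all table writers
fmt_num <- function(x, digits = 4) {
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}
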