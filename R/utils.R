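#' Round half away from zero
#'
#' T-scores, thresholds and percentages in published reference tables are
#' rounded with the "half-up" convention (0.5 always rounds away from zero),
#' not the IEEE round-half-even used by [base::round()].  All user-facing
#' rounding in this package goes through this one function.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @examples
#' round_half_up(50.5)   # 51, where round(50.5) gives 50
#' round_half_up(44.65, 1)
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  # nudge by a relative epsilon so values stored as 44.649999... still round
  # the way their printed decimal does
  z <- abs(x) * m
  sign(x) * floor(z + 0.5 + 1e-9) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with call. = FALSE everywhere; small wrapper keeps messages uniform
fail <- function(...) stop(..., call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
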