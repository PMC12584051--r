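#' Round half away from zero
#'
#' Commercial ("kaufmaennisch") rounding: halves move away from zero, so
#' 2.5 -> 3 and -2.5 -> -3. Base [round()] uses IEC 60559 half-to-even,
#' which is unsuitable for fee computation where the statutory rule is
#' half-up on the final cent amount.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return `x` rounded to `digits` places, halves away from zero.
#' @examples
#' round_half_away(2.5)        # 3, where round(2.5) gives 2
#' round_half_away(37.537, 2)  # 37.54
#' @export
round_half_away <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  p <- 10^digits
  # tiny guard absorbs binary representation error in products like 4.6 * 100
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# Internal: rounding of the rubric mean under the configured rule.
round_mean <- function(x, rounding = c("half_up", "half_even")) {
  rounding <- match.arg(rounding)
  if (rounding == "half_up") round_half_away(x) else round(x)
}

# Internal: scalar validation helpers used across modules.
assert_rate <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single rate in [0, 1], got %s",
                 name, deparse(x)), call. = FALSE)
  }
  invisible(x)
}

assert_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0) {
    stop(sprintf("`%s` must be a single non-negative number, got %s",
                 name, deparse(x)), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
      x != trunc(x)) {
    stop(sprintf("`%s` must be a single integer >= %d, got %s",
                 name, min, deparse(x)), call. = FALSE)
  }
  invisible(as.integer(x))
}
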