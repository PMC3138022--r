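# Internal helpers shared across the package.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Decimal rounding in which ties are rounded away from zero ("half-up" for
#' positive values), so `round_half_up(3.75, 1)` is `3.8`. Base R's
#' [round()] uses banker's rounding (half-even), which would give `3.8` here
#' too but `0.25 -> 0.2`; reported MCR values in this package follow the
#' half-up convention at one decimal.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return numeric vector of `x` rounded to `digits` decimals.
#' @examples
#' round_half_up(3.75, 1) # 3.8
#' round_half_up(0.25, 1) # 0.3 (base round() gives 0.2)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# stop() without the call, with sprintf-style formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# scalar type checks used by constructors
check_positive_scalar <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    abort("%s must be a single positive finite number", what)
  invisible(x)
}

# Normalize chemical names for matching: trim, collapse internal whitespace,
# lower-case. No fuzzy matching by design -- a silent mis-join is worse than
# a loud miss.
normalize_chemical <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(as.character(x))))
}
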