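# Internal helpers shared across modules.

# Round half away from zero to `digits` decimals (table formatting convention;
# base round() is half-to-even).
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a proportion as a percentage
#'
#' Converts a proportion in \[0, 1\] to a percentage rounded to one decimal,
#' half away from zero — the convention used throughout the package's
#' evaluation tables.
#'
#' @param x Numeric vector of proportions.
#' @param digits Decimal places to keep (default 1).
#' @return Numeric vector on the 0–100 scale.
#' @examples
#' as_percent(c(0.83066, 0.905))
#' @export
as_percent <- function(x, digits = 1) {
  round_half_away(100 * x, digits)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_prob <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    abort(sprintf("`%s` must be numeric in [0, 1].", what))
  }
  invisible(x)
}

# Shortest decimal representation that parses back to the identical double
# (15 -> 16 -> 17 significant digits); keeps CSV round-trips bit-exact.
format_roundtrip <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  out[ok] <- sprintf("%.15g", x[ok])
  for (digits in c("%.16g", "%.17g")) {
    bad <- ok & suppressWarnings(as.numeric(out)) != x
    bad[is.na(bad)] <- FALSE
    if (!any(bad)) break
    out[bad] <- sprintf(digits, x[bad])
  }
  out
}

# stable row-wise softmax of a matrix
softmax_rows <- function(S) {
  Z <- exp(S - apply(S, 1, max))
  Z / rowSums(Z)
}
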