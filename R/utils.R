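#' Round half-up
#'
#' Base R's `round()` rounds half to even; report tables here follow the
#' half-up convention (0.005 -> 0.01), applied after a tiny nudge that guards
#' against binary representation error in values such as `84.045`.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  floor(x * m + 0.5 + 1e-9) / m
}

#' Format a proportion as a 2-decimal percentage string
#'
#' `format_percent(353, 420)` returns `"84.05"`, the convention used by the
#' report tables: `100 * count / total`, rounded half-up to two decimals.
#'
#' @param count Numerator count (non-negative).
#' @param total Denominator count (strictly positive).
#' @return Character vector of 2-decimal percentage strings (no `%` sign).
#' @examples
#' format_percent(353, 420)
#' format_percent(1, 3)
#' @export
format_percent <- function(count, total) {
  if (any(total <= 0)) abort("`total` must be strictly positive.")
  sprintf("%.2f", round_half_up(100 * count / total, 2))
}

# Derive a per-stage child seed from the run seed; keeps every derived seed a
# valid 32-bit integer.
derive_seed <- function(seed, stage) {
  as.integer((as.double(seed) + 104729 * stage) %% 2147483629L)
}

# sample() treats a length-1 numeric as 1:x; this never does.
resample <- function(x, n) x[sample.int(length(x), n)]

# Internal input checkers ------------------------------------------------

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    abort(sprintf("`%s` must be a single probability in [0, 1].", name))
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x))
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  invisible(as.integer(x))
}
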