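#' Percentage of a count, rounded for reporting
#'
#' Formats `n` out of `total` as a percentage rounded to a fixed number of
#' decimals, the convention used throughout the screen and proteome summary
#' reports (e.g. 236 obvious-synergy pairs of 1225 -> 19.3).
#'
#' @param n Numerator count (non-negative).
#' @param total Denominator count (> 0).
#' @param digits Decimals to keep (default 1).
#' @return A bare numeric percentage on the 0-100 scale.
#' @examples
#' percent_of(236, 1225) # 19.3
#' percent_of(314, 4974, digits = 2) # 6.31
#' @export
percent_of <- function(n, total, digits = 1) {
  stopifnot(is.numeric(n), is.numeric(total))
  if (any(total <= 0)) abort("`total` must be positive.")
  if (any(n < 0)) abort("`n` must be non-negative.")
  round(100 * n / total, digits)
}

#' Four-parameter logistic viability at a dose
#'
#' The decreasing 4PL curve used by both the screen simulator and the
#' dose-response fitter: `bottom + (top - bottom) / (1 + (dose/ic50)^hill)`.
#' At `dose = ic50` the curve sits halfway between `top` and `bottom`.
#'
#' @param dose Dose(s), same concentration units as `ic50` (conventionally uM).
#' @param ic50 Curve midpoint (> 0).
#' @param hill Hill slope (> 0).
#' @param top,bottom Asymptotic viabilities at zero and saturating dose.
#' @return Predicted fractional viability, same length as `dose`.
#' @export
viability_4pl <- function(dose, ic50, hill, top = 1, bottom = 0) {
  bottom + (top - bottom) / (1 + (dose / ic50)^hill)
}

# multiplicative lognormal noise with mean exactly 1 and the stated CV
rlnorm_cv <- function(n, cv) {
  if (cv < 0) abort("noise CV must be >= 0.")
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# run `expr` under a local RNG seeded with `seed`, restoring global state
with_seed <- function(seed, expr) {
  if (is.null(seed)) abort("a `seed` is required.")
  withr::with_seed(as.integer(seed), expr)
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}
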