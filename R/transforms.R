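#' Inverse hyperbolic sine transform
#'
#' Computes `log(x + sqrt(x^2 + 1))`, a log-like transform that is defined
#' at zero (and for negative values). It is the natural scale for per-type
#' richness counts, where a plot-year may contain zero species of a given
#' type and `log()` would be undefined. For large `x`, `ihs(x)` approaches
#' `log(2 * x)`.
#'
#' @param x Numeric vector (or matrix); typically non-negative counts.
#' @return Numeric object of the same shape as `x`.
#' @examples
#' ihs(0)            # 0
#' ihs(1)            # log(1 + sqrt(2))
#' ihs(1000) - log(2000)  # ~ 0
#' @export
ihs <- function(x) {
  stopifnot(is.numeric(x))
  # asinh() is the same function; spelled out to keep the defining identity
  # visible next to its documentation.
  log(x + sqrt(x^2 + 1))
}

#' Elasticity reporting helpers
#'
#' In a ln-ln regression the slope `beta` is an elasticity: the expected
#' percent change in the outcome per one percent change in the regressor.
#' The effect of a 10 percent increase in the regressor is commonly
#' linearized as `10 * beta` percent; the exact value is
#' `100 * (1.1^beta - 1)` percent. Both are returned.
#'
#' @param beta Elasticity (ln-ln slope).
#' @return Named numeric vector with elements `pct_per_10pct_linear`
#'   (`10 * beta`) and `pct_per_10pct_exact` (`100 * (1.1^beta - 1)`).
#' @export
elasticity_pct10 <- function(beta) {
  c(pct_per_10pct_linear = 10 * beta,
    pct_per_10pct_exact  = 100 * (1.1^beta - 1))
}
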