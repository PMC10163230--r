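#' Instrumental-variables (two-stage least squares) design
#'
#' Estimates the richness elasticity using an excluded instrument: a
#' variable that shifts richness but affects productivity only through
#' richness (in the study's setting, the mean richness of neighboring
#' nutrient-manipulated plots in the same block). Plot and site-by-year
#' fixed effects are absorbed from ln biomass, ln richness and the
#' instrument; the first stage regresses residualized ln richness on the
#' residualized instrument, and the second stage regresses residualized
#' ln biomass on the first-stage fitted values. Standard errors follow
#' the 2SLS convention: second-stage residuals are recomputed with the
#' observed (not fitted) ln richness before entering the CR1 clustered
#' sandwich.
#'
#' In the just-identified single-instrument case the 2SLS point estimate
#' equals the reduced-form coefficient divided by the first-stage
#' coefficient, and the heteroskedasticity/cluster-robust effective
#' F-statistic for instrument strength is the squared first-stage
#' coefficient over its cluster-robust variance.
#'
#' @param panel A `bef_panel` with an instrument column.
#' @param instrument Name of the instrument column.
#' @param cluster_level `"plot"` (default) or `"site"`.
#' @param conf_level Confidence level for intervals.
#' @return An object of class `bef_iv_fit`: a `bef_fit` for the second
#'   stage (term `fitted_ln_richness` carries beta) plus `first_stage`
#'   (coefficient, SE, CI), `F_effective`, `F_classical`, and `n_dropped`
#'   (rows lost to a missing instrument).
#' @export
estimate_iv <- function(panel, instrument = "instrument",
                        cluster_level = "plot", conf_level = 0.95) {
  if (!instrument %in% names(panel)) {
    stop("instrument column absent from panel: ", instrument)
  }
  z <- as.numeric(panel[[instrument]])
  keep <- !is.na(z) & !is.na(panel$live_mass) & !is.na(panel$richness)
  n_dropped <- sum(!keep)
  panel <- panel[keep, , drop = FALSE]
  z <- z[keep]
  y <- log(panel$live_mass)
  x <- log(panel$richness)
  factors <- fe_factors(panel, fe_spec(plot = TRUE, site_year = TRUE))
  cluster <- panel_cluster(panel, cluster_level)
  df_abs <- fe_degrees_of_freedom(factors)

  ab <- absorb_fixed_effects(cbind(y = y, x = x, z = z), factors)
  yt <- ab$x[, "y"]; xt <- ab$x[, "x"]; zt <- ab$x[, "z"]
  if (stats::var(zt) < 1e-14) {
    stop("instrument has no variation after fixed-effect absorption")
  }

  # first stage: x~ on z~
  fs <- ols_fit(xt, cbind(z = zt))
  fs_cr <- cluster_robust_vcov(fs, cluster, df_absorbed = df_abs)
  gamma <- fs$coefficients[["z"]]
  gamma_se <- sqrt(fs_cr$vcov["z", "z"])
  F_effective <- gamma^2 / fs_cr$vcov["z", "z"]
  # classical homoskedastic first-stage F
  s2 <- sum(fs$residuals^2) / (fs$n - 1L - df_abs)
  F_classical <- gamma^2 / (s2 * fs$XtX_inv["z", "z"])

  xhat <- fs$fitted
  ss <- ols_fit(yt, cbind(fitted_ln_richness = xhat))
  beta <- ss$coefficients[["fitted_ln_richness"]]
  # 2SLS residuals use the observed regressor
  u <- yt - beta * xt
  ss$residuals <- u
  ss_cr <- cluster_robust_vcov(ss, cluster, df_absorbed = df_abs)

  fit <- new_bef_fit(ss, ss_cr, y_within = yt, y_raw = y, design = "iv",
                     cluster_level = cluster_level, df_absorbed = df_abs,
                     fe = names(factors), conf_level = conf_level)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, fs_cr$n_clusters - 1L)
  fit$first_stage <- data.frame(term = instrument, estimate = gamma,
                                se = gamma_se,
                                conf_low = gamma - tcrit * gamma_se,
                                conf_high = gamma + tcrit * gamma_se)
  fit$F_effective <- unname(F_effective)
  fit$F_classical <- unname(F_classical)
  fit$n_dropped <- n_dropped
  class(fit) <- c("bef_iv_fit", class(fit))
  fit
}

#' @export
print.bef_iv_fit <- function(x, ...) {
  NextMethod()
  cat(sprintf("first stage: gamma = %.4f (SE %.4f); effective F = %.2f, classical F = %.2f\n",
              x$first_stage$estimate, x$first_stage$se,
              x$F_effective, x$F_classical))
  invisible(x)
}

#' Build a block-mean instrument from neighbor richness
#'
#' Convenience helper for data where each unmanipulated plot sits in a
#' block of manipulated plots: the instrument for a focal plot-year is
#' the mean richness of the other plots in the same group (block) and
#' year.
#'
#' @param df Data frame with `year`, `richness` and a grouping column.
#' @param group Name of the block/group column.
#' @return Numeric vector (aligned with `df` rows): leave-one-out group
#'   mean richness; `NA` for singleton group-years.
#' @export
neighbor_mean_instrument <- function(df, group = "site_id") {
  g <- interaction(df[[group]], df$year, drop = TRUE)
  tot <- stats::ave(df$richness, g, FUN = sum)
  cnt <- stats::ave(df$richness, g, FUN = length)
  out <- (tot - df$richness) / (cnt - 1)
  out[cnt < 2] <- NA_real_
  out
}
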