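#' Mechanism-blocking design for reverse causality
#'
#' Re-estimates the two-way fixed-effects design with the shading
#' covariate (fraction of ground-level light intercepted, in \[0, 1\])
#' added as a regressor. If productivity affected richness through
#' shading, conditioning on shading blocks that back-path; a richness
#' coefficient that is unchanged relative to the plain design is evidence
#' that reverse causality via shading is not driving the estimate.
#'
#' Because richness in a recursive annual system responds to the shading
#' it experienced during establishment -- the previous season's -- the
#' blocking covariate is by default the one-year-lagged shade, built
#' within plots from consecutive years (current-season shade is itself a
#' near-deterministic consequence of current biomass, so conditioning on
#' it would partial out the outcome rather than block the back-path).
#' Set `lag = FALSE` for data where the measured shading is a
#' contemporaneous proxy.
#'
#' @param panel A `bef_panel` with a `shade` column.
#' @param lag Use the one-year-lagged shade (default) or the current one.
#' @param cluster_level `"plot"` (default) or `"site"`.
#' @return A `bef_fit` (design label `"mechanism_block"`) whose terms
#'   include both `ln_richness` and the shade covariate.
#' @export
estimate_mechanism_block <- function(panel, lag = TRUE, cluster_level = "plot") {
  if (!"shade" %in% names(panel)) {
    stop("mechanism-blocking design needs a 'shade' column")
  }
  sh <- panel$shade
  if (any(sh < 0 | sh > 1, na.rm = TRUE)) {
    stop("'shade' must be a fraction in [0, 1]")
  }
  df <- as.data.frame(panel)
  if (lag) {
    df <- df[order(df$plot_id, df$year), , drop = FALSE]
    prev_plot <- c(NA, df$plot_id[-nrow(df)])
    prev_year <- c(NA, df$year[-nrow(df)])
    prev_shade <- c(NA, df$shade[-nrow(df)])
    has_lag <- !is.na(prev_plot) & prev_plot == df$plot_id &
      df$year - prev_year == 1L
    if (!any(has_lag)) stop("no consecutive-year pairs; cannot lag shade")
    df$shade_lag <- ifelse(has_lag, prev_shade, NA_real_)
    df <- df[has_lag, , drop = FALSE]
    cov_name <- "shade_lag"
  } else {
    cov_name <- "shade"
  }
  X <- cbind(ln_richness = log(df$richness), df[[cov_name]])
  colnames(X)[2L] <- cov_name
  fit <- fit_design(
    y = log(df$live_mass), X = X, data = df,
    factors = fe_factors(df, fe_spec(plot = TRUE, site_year = TRUE)),
    cluster = panel_cluster(df, cluster_level),
    design = "mechanism_block", cluster_level = cluster_level)
  fit
}

#' Lagged-dependent-variable (dynamic panel) design
#'
#' Regresses ln biomass on ln richness and the previous year's ln biomass
#' with site-by-year fixed effects (and no plot fixed effects: combining
#' a lagged outcome with unit fixed effects in a short panel induces
#' Nickell bias, and the design's identifying assumption -- plot-level
#' confounding operates through prior productivity -- replaces the
#' fixed-effects assumption rather than supplementing it). The lag is
#' built within plots from strictly consecutive years; each plot's first
#' usable year (and any year without a year-before observation) is
#' dropped.
#'
#' @param panel A `bef_panel`.
#' @param cluster_level `"plot"` (default) or `"site"`.
#' @return A `bef_fit` (design `"ldv"`) with terms `ln_richness` (beta)
#'   and `ln_live_mass_lag` (theta), and `n_dropped_lag` rows lost to lag
#'   construction.
#' @export
estimate_ldv <- function(panel, cluster_level = "plot") {
  df <- as.data.frame(panel)
  df <- df[order(df$plot_id, df$year), , drop = FALSE]
  prev_plot <- c(NA, df$plot_id[-nrow(df)])
  prev_year <- c(NA, df$year[-nrow(df)])
  prev_mass <- c(NA, df$live_mass[-nrow(df)])
  has_lag <- !is.na(prev_plot) & prev_plot == df$plot_id &
    df$year - prev_year == 1L
  if (!any(has_lag)) stop("no consecutive-year pairs; cannot build the lag")
  df$ln_live_mass_lag <- ifelse(has_lag, log(prev_mass), NA_real_)
  n_dropped <- sum(!has_lag)
  df <- df[has_lag, , drop = FALSE]

  fit <- fit_design(
    y = log(df$live_mass),
    X = cbind(ln_richness = log(df$richness),
              ln_live_mass_lag = df$ln_live_mass_lag),
    data = df,
    factors = fe_factors(df, fe_spec(plot = FALSE, site_year = TRUE)),
    cluster = panel_cluster(df, cluster_level),
    design = "ldv", cluster_level = cluster_level)
  fit$n_dropped_lag <- n_dropped
  fit
}

#' Bracketing interval from the fixed-effects and LDV designs
#'
#' Under either design's assumption set, the two-way fixed-effects
#' estimate and the lagged-dependent-variable estimate bound the true
#' effect: if the fixed-effects assumptions hold the LDV estimate is
#' biased toward the confounded direction and vice versa. The interval is
#' the ordered pair of estimates; a substantive conclusion (shared sign)
#' is reported only when both endpoints agree in sign.
#'
#' @param beta_main Estimate from the two-way fixed-effects design (or a
#'   `bef_fit`).
#' @param beta_ldv Estimate from the LDV design (or a `bef_fit`).
#' @return List with `interval` (sorted length-2 numeric),
#'   `sign_agreement` (logical) and `conclusion` (character, only
#'   meaningful when signs agree).
#' @export
bracket <- function(beta_main, beta_ldv) {
  if (inherits(beta_main, "bef_fit")) beta_main <- beta_richness(beta_main)
  if (inherits(beta_ldv, "bef_fit")) beta_ldv <- beta_richness(beta_ldv)
  interval <- sort(c(beta_main, beta_ldv))
  agree <- prod(sign(interval)) > 0
  conclusion <- if (!agree) {
    "estimates differ in sign; no bracketing conclusion"
  } else if (interval[2] < 0) {
    "both designs negative: bracketed effect is negative"
  } else {
    "both designs positive: bracketed effect is positive"
  }
  list(beta_main = beta_main, beta_ldv = beta_ldv,
       interval = interval, sign_agreement = agree, conclusion = conclusion)
}
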