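#' Simulation configuration for the synthetic grassland panel
#'
#' Bundles every parameter of the data-generating process: the panel
#' dimensions, the true richness elasticity, the variance and correlation
#' of each confounding channel (time-invariant plot, site-by-year,
#' plot-by-year), the excluded instrument's first-stage strength, the
#' lagged reverse-causality channel through shading, and the community
#' (rank-abundance) model used to simulate species cover.
#'
#' Confounding is induced by bivariate Gaussian loadings: each channel
#' draws a pair (loading on ln richness, loading on ln biomass) with the
#' channel's standard deviation and correlation `rho_*`. A positive `rho`
#' makes the channel push richness and biomass in the same direction,
#' which biases naive estimators upward.
#'
#' @param n_sites Number of sites.
#' @param plots_per_site Plots per site.
#' @param n_years Observed years per plot (balanced panel).
#' @param beta_true True elasticity of biomass with respect to richness
#'   (ln-ln slope).
#' @param beta_by_type Named 4-vector of per-type effects on the inverse
#'   hyperbolic sine of per-type richness, used only when
#'   `simulate_panel(..., by_type = TRUE)`; names
#'   `rare_native`, `nonrare_native`, `nonrare_nonnative`, `rare_nonnative`.
#' @param sd_plot_confounder,sd_siteyear_confounder,sd_plotyear_confounder
#'   Standard deviations of the loading pairs for each confounding channel.
#' @param rho_plot,rho_siteyear,rho_plotyear Correlation (in [-1, 1])
#'   between each channel's loading on ln richness and on ln biomass.
#' @param instrument_strength First-stage coefficient of the standard
#'   normal instrument on ln richness.
#' @param reverse_lambda Coefficient of last year's (centered) shading on
#'   this year's ln richness; nonzero values create reverse causality with
#'   a one-year lag.
#' @param persistence_theta Autoregressive coefficient of (centered) ln
#'   biomass on its own one-year lag. Combined with `reverse_lambda` this
#'   makes last year's productivity drive both current richness and
#'   current productivity -- the confounding world the
#'   lagged-dependent-variable design is built for.
#' @param sd_noise Standard deviation of the idiosyncratic ln-biomass error.
#' @param sd_richness_shock Standard deviation of the idiosyncratic
#'   ln-richness shock (the clean, exclusion-satisfying variation).
#' @param sd_covariate_noise Measurement noise (as a multiple of each
#'   latent confounder's SD) on the observed covariate columns emitted with
#'   the panel; `0` means confounders are observed perfectly.
#' @param pool_size Species pool size per site; must exceed the largest
#'   achievable richness.
#' @param rank_abundance_decay Geometric-series parameter in (0, 1):
#'   relative abundance of the rank-k species is proportional to
#'   `decay^k`.
#' @param frac_nonnative Probability that a pool species is non-native.
#' @param rarity_cutoff Relative-abundance threshold below which a pool
#'   species is rare.
#' @param mean_log_richness,mean_log_biomass Baseline intercepts of the
#'   two structural equations (log scale; defaults give a median richness
#'   near 10 species and biomass near 300 g/m^2).
#' @param shade_scale Logistic scale linking ln biomass to the shading
#'   fraction.
#' @param seed Integer seed; the same config and seed reproduce the panel
#'   bit for bit.
#' @return A validated `sim_config` object (a list).
#' @export
sim_config <- function(n_sites = 43L,
                       plots_per_site = 4L,
                       n_years = 8L,
                       beta_true = -0.24,
                       beta_by_type = c(rare_native = -0.05,
                                        nonrare_native = 0.08,
                                        nonrare_nonnative = -0.08,
                                        rare_nonnative = -0.02),
                       sd_plot_confounder = 0.3,
                       sd_siteyear_confounder = 0.2,
                       sd_plotyear_confounder = 0,
                       rho_plot = 0.5,
                       rho_siteyear = 0.5,
                       rho_plotyear = 0.5,
                       instrument_strength = 0.2,
                       reverse_lambda = 0,
                       persistence_theta = 0,
                       sd_noise = 0.35,
                       sd_richness_shock = 0.3,
                       sd_covariate_noise = 0.3,
                       pool_size = 60L,
                       rank_abundance_decay = 0.85,
                       frac_nonnative = 0.25,
                       rarity_cutoff = 0.05,
                       mean_log_richness = log(10),
                       mean_log_biomass = log(300),
                       shade_scale = 1,
                       seed = 1L) {
  cfg <- list(n_sites = as.integer(n_sites),
              plots_per_site = as.integer(plots_per_site),
              n_years = as.integer(n_years),
              beta_true = beta_true,
              beta_by_type = beta_by_type,
              sd_plot_confounder = sd_plot_confounder,
              sd_siteyear_confounder = sd_siteyear_confounder,
              sd_plotyear_confounder = sd_plotyear_confounder,
              rho_plot = rho_plot,
              rho_siteyear = rho_siteyear,
              rho_plotyear = rho_plotyear,
              instrument_strength = instrument_strength,
              reverse_lambda = reverse_lambda,
              persistence_theta = persistence_theta,
              sd_noise = sd_noise,
              sd_richness_shock = sd_richness_shock,
              sd_covariate_noise = sd_covariate_noise,
              pool_size = as.integer(pool_size),
              rank_abundance_decay = rank_abundance_decay,
              frac_nonnative = frac_nonnative,
              rarity_cutoff = rarity_cutoff,
              mean_log_richness = mean_log_richness,
              mean_log_biomass = mean_log_biomass,
              shade_scale = shade_scale,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_sites < 1L || plots_per_site < 1L || n_years < 1L) {
      stop("panel dimensions must be positive")
    }
    sds <- c(sd_plot_confounder, sd_siteyear_confounder,
             sd_plotyear_confounder, sd_noise, sd_richness_shock,
             sd_covariate_noise)
    if (any(sds < 0)) stop("standard deviations must be non-negative")
    rhos <- c(rho_plot, rho_siteyear, rho_plotyear)
    if (any(abs(rhos) > 1)) stop("correlations must lie in [-1, 1]")
    if (rank_abundance_decay <= 0 || rank_abundance_decay >= 1) {
      stop("rank_abundance_decay must lie in (0, 1)")
    }
    if (frac_nonnative < 0 || frac_nonnative > 1) {
      stop("frac_nonnative must lie in [0, 1]")
    }
    if (rarity_cutoff <= 0 || rarity_cutoff >= 1) {
      stop("rarity_cutoff must lie in (0, 1)")
    }
    if (length(beta_by_type) != 4L) stop("beta_by_type must have 4 elements")
    if (pool_size < 1L) stop("pool_size must be positive")
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d sites x %d plots x %d years; beta_true = %g; seed = %d\n",
              x$n_sites, x$plots_per_site, x$n_years, x$beta_true, x$seed))
  cat(sprintf("  confounders (sd, rho): plot (%g, %g), site-year (%g, %g), plot-year (%g, %g)\n",
              x$sd_plot_confounder, x$rho_plot,
              x$sd_siteyear_confounder, x$rho_siteyear,
              x$sd_plotyear_confounder, x$rho_plotyear))
  cat(sprintf("  instrument gamma = %g; reverse lambda = %g; persistence theta = %g\n",
              x$instrument_strength, x$reverse_lambda, x$persistence_theta))
  invisible(x)
}

#' Named simulation scenarios
#'
#' Pre-registered parameterizations of [sim_config()] used throughout the
#' package's validation suite:
#'
#' * `"paper_like"` -- study-scale panel (43 sites x 4 plots x 8 years)
#'   with every channel active: plot and site-by-year confounding, a
#'   plot-by-year confounder, a valid instrument, and lagged reverse
#'   causality through shading.
#' * `"confounded"` -- the default recovery scenario
#'   (10 sites x 4 plots x 6 years): positive plot and site-by-year
#'   confounding, no plot-by-year confounding, so the two-way
#'   fixed-effects design is consistent while naive designs are biased
#'   upward.
#' * `"signflip"` -- negative true elasticity with strong positive
#'   site-by-year confounding, so designs that fail to absorb site-year
#'   shocks estimate a positive effect.
#' * `"iv"` -- plot-by-year confounding (which the two-way design cannot
#'   remove) plus a strong valid instrument.
#' * `"reverse"` -- a strong lagged shading channel plus productivity
#'   persistence, so last year's productivity confounds the
#'   richness-productivity relation; for the mechanism-blocking design.
#' * `"ldv_world"` -- the lagged-dependent-variable design's assumption
#'   set: no time-invariant plot confounding, but last year's
#'   productivity drives both current richness (through shading) and
#'   current productivity (persistence).
#' * `"null"` -- zero effect and no confounding.
#' * `"ideal"` -- no confounding, no reverse causality; every design
#'   should recover `beta_true`.
#'
#' @param name Scenario name.
#' @param seed Integer seed.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_scenario <- function(name = c("paper_like", "confounded", "signflip",
                                  "iv", "reverse", "ldv_world", "null",
                                  "ideal"),
                         seed = 1L, ...) {
  name <- match.arg(name)
  args <- switch(name,
    paper_like = list(sd_plotyear_confounder = 0.15, rho_plotyear = 0.5,
                      instrument_strength = 0.3, reverse_lambda = 0.4,
                      persistence_theta = 0.3),
    confounded = list(n_sites = 10L, plots_per_site = 4L, n_years = 6L),
    signflip = list(n_sites = 10L, plots_per_site = 4L, n_years = 6L,
                    sd_siteyear_confounder = 0.4, rho_siteyear = 0.9,
                    rho_plot = 0.6),
    iv = list(n_sites = 10L, plots_per_site = 4L, n_years = 6L,
              sd_plot_confounder = 0.2, sd_siteyear_confounder = 0.15,
              sd_plotyear_confounder = 0.2, rho_plotyear = 0.7,
              instrument_strength = 0.4),
    reverse = list(n_sites = 10L, plots_per_site = 4L, n_years = 6L,
                   sd_plot_confounder = 0.2, sd_siteyear_confounder = 0.15,
                   reverse_lambda = 0.8, persistence_theta = 0.5),
    ldv_world = list(n_sites = 10L, plots_per_site = 4L, n_years = 6L,
                     sd_plot_confounder = 0, sd_siteyear_confounder = 0.15,
                     reverse_lambda = 0.8, persistence_theta = 0.5),
    null = list(n_sites = 10L, plots_per_site = 4L, n_years = 6L,
                beta_true = 0, sd_plot_confounder = 0,
                sd_siteyear_confounder = 0, sd_plotyear_confounder = 0),
    ideal = list(n_sites = 10L, plots_per_site = 4L, n_years = 6L,
                 sd_plot_confounder = 0, sd_siteyear_confounder = 0,
                 sd_plotyear_confounder = 0))
  user <- list(...)
  args[names(user)] <- user
  do.call(sim_config, c(args, list(seed = seed)))
}

#' Write / read a simulation configuration as YAML
#'
#' @param config A `sim_config`.
#' @param path File path.
#' @return `read_sim_config_yaml()` returns a `sim_config`.
#' @export
write_sim_config_yaml <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to write YAML configs")
  }
  vals <- unclass(config)
  vals$beta_by_type <- as.list(vals$beta_by_type)   # keep the type names
  yaml::write_yaml(vals, path, precision = 15)
  invisible(path)
}

#' @rdname write_sim_config_yaml
#' @export
read_sim_config_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configs")
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  bt <- vals$beta_by_type
  if (!is.null(bt)) vals$beta_by_type <- unlist(bt)
  do.call(sim_config, vals)
}
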