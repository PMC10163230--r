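#' Simulate a longitudinal grassland panel with known ground truth
#'
#' Generates a balanced plot-by-site-by-year panel from a recursive
#' structural model that encodes every arrow of the study's causal
#' diagram:
#'
#' * ln richness is driven by a baseline, the richness loadings of the
#'   plot, site-by-year and plot-by-year confounders, the excluded
#'   instrument `Z` (standard normal, first-stage coefficient
#'   `instrument_strength`), last year's centered shading times
#'   `reverse_lambda` (the lagged reverse-causality channel), and an
#'   idiosyncratic shock;
#' * observed richness is `max(1, round(exp(ln richness)))`, capped at the
#'   species pool size (estimation then uses the log of this integer,
#'   which introduces mild discretization noise);
#' * ln biomass is the true elasticity times the log of observed richness
#'   plus the biomass loadings of the same confounders, an optional
#'   autoregressive term `persistence_theta` times last year's centered
#'   ln biomass, and a noise term; with `by_type = TRUE` the single
#'   elasticity is replaced by the four per-type effects on `ihs()` of
#'   per-type richness, with types taken from the site's simulated
#'   species pool;
#' * shading is a logistic function of ln biomass (fraction of light
#'   intercepted, in \[0, 1\]), which closes the reverse-causality loop
#'   with a one-year lag.
#'
#' Confounder loading pairs are bivariate Gaussian with the configured
#' standard deviation and correlation per channel. The panel also carries
#' observed covariates `cov_plot` and `cov_siteyear`: the biomass-side
#' confounder loadings plus Gaussian measurement noise of
#' `sd_covariate_noise` times the channel SD, which is what a
#' conditioning-on-observables design gets to adjust for.
#'
#' @param config A [sim_config()].
#' @param by_type If `TRUE`, biomass responds to the four rarity-by-origin
#'   richness components instead of total richness; the species pool and
#'   plot-year communities are simulated jointly and returned.
#' @return List with `panel` (a `bef_panel` with columns `site_id`,
#'   `plot_id`, `year`, `live_mass`, `richness`, `shade`, `instrument`,
#'   `cov_plot`, `cov_siteyear`, and with `by_type` also `R_rare_native`,
#'   `R_nonrare_native`, `R_nonrare_nonnative`, `R_rare_nonnative`),
#'   `truth` (list: the config, the latent draws per unit, and the latent
#'   continuous ln richness / ln biomass before discretization), and with
#'   `by_type` also `cover` (the simulated cover table) and `pool`
#'   (per-site species pool with true abundances, origin and type).
#' @export
simulate_panel <- function(config, by_type = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  S <- config$n_sites; P <- config$plots_per_site; T <- config$n_years
  n_plots <- S * P

  site_id <- sprintf("site%02d", seq_len(S))
  plot_tab <- data.frame(
    site_id = rep(site_id, each = P),
    plot_id = sprintf("plot%03d", seq_len(n_plots)),
    stringsAsFactors = FALSE)

  # bivariate Gaussian loading pairs (on ln richness, on ln biomass)
  draw_pair <- function(n, sd, rho) {
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    cbind(r = sd * z1, p = sd * (rho * z1 + sqrt(1 - rho^2) * z2))
  }
  plot_load <- draw_pair(n_plots, config$sd_plot_confounder, config$rho_plot)
  sy_load <- draw_pair(S * T, config$sd_siteyear_confounder, config$rho_siteyear)
  py_load <- draw_pair(n_plots * T, config$sd_plotyear_confounder, config$rho_plotyear)

  sy_index <- function(s, t) (s - 1L) * T + t   # s, t integer indices
  site_of_plot <- rep(seq_len(S), each = P)

  Z <- matrix(stats::rnorm(n_plots * T), n_plots, T)
  u_r <- matrix(stats::rnorm(n_plots * T, sd = config$sd_richness_shock), n_plots, T)
  eps_p <- matrix(stats::rnorm(n_plots * T, sd = config$sd_noise), n_plots, T)

  pool <- NULL; cover_rows <- NULL
  if (by_type) {
    pool <- simulate_species_pool(config)
    cover_rows <- vector("list", n_plots * T)
  }

  lnR_lat <- lnP_lat <- shade <- matrix(NA_real_, n_plots, T)
  richness <- matrix(NA_integer_, n_plots, T)
  Rk <- array(0L, dim = c(n_plots, T, 4L),
              dimnames = list(NULL, NULL, names(config$beta_by_type)))
  shade_prev <- rep(0.5, n_plots)   # centered: no reverse pressure in year 1
  lnP_prev <- rep(config$mean_log_biomass, n_plots)  # no persistence in year 1

  for (t in seq_len(T)) {
    syi <- sy_index(site_of_plot, t)
    pyi <- (seq_len(n_plots) - 1L) * T + t
    lnR <- config$mean_log_richness + plot_load[, "r"] + sy_load[syi, "r"] +
      py_load[pyi, "r"] + config$instrument_strength * Z[, t] +
      config$reverse_lambda * (shade_prev - 0.5) + u_r[, t]
    R_obs <- pmin(config$pool_size, pmax(1L, as.integer(round(exp(lnR)))))

    if (by_type) {
      for (i in seq_len(n_plots)) {
        draw <- draw_community(pool[[site_of_plot[i]]], R_obs[i])
        Rk[i, t, ] <- draw$type_counts
        cover_rows[[(i - 1L) * T + t]] <- data.frame(
          site_id = plot_tab$site_id[i], plot_id = plot_tab$plot_id[i],
          year = 2000L + t, species_id = draw$species_id,
          relative_cover = draw$relative_cover, origin = draw$origin,
          stringsAsFactors = FALSE)
      }
      effect <- Rk[, t, , drop = FALSE]
      dim(effect) <- c(n_plots, 4L)
      lnP <- config$mean_log_biomass +
        drop(ihs(effect) %*% config$beta_by_type) +
        config$persistence_theta * (lnP_prev - config$mean_log_biomass) +
        plot_load[, "p"] + sy_load[syi, "p"] + py_load[pyi, "p"] + eps_p[, t]
    } else {
      lnP <- config$mean_log_biomass + config$beta_true * log(R_obs) +
        config$persistence_theta * (lnP_prev - config$mean_log_biomass) +
        plot_load[, "p"] + sy_load[syi, "p"] + py_load[pyi, "p"] + eps_p[, t]
    }
    sh <- stats::plogis((lnP - config$mean_log_biomass) / config$shade_scale)

    lnR_lat[, t] <- lnR; lnP_lat[, t] <- lnP
    richness[, t] <- R_obs; shade[, t] <- sh
    shade_prev <- sh
    lnP_prev <- lnP
  }

  mnoise <- function(latent, sd_channel) {
    latent + stats::rnorm(length(latent),
                          sd = config$sd_covariate_noise * sd_channel)
  }
  cov_plot_obs <- mnoise(plot_load[, "p"], config$sd_plot_confounder)
  cov_sy_obs <- mnoise(sy_load[, "p"], config$sd_siteyear_confounder)

  idx_plot <- rep(seq_len(n_plots), times = T)
  idx_year <- rep(seq_len(T), each = n_plots)
  panel <- data.frame(
    site_id = plot_tab$site_id[idx_plot],
    plot_id = plot_tab$plot_id[idx_plot],
    year = 2000L + idx_year,
    live_mass = exp(lnP_lat[cbind(idx_plot, idx_year)]),
    richness = richness[cbind(idx_plot, idx_year)],
    shade = shade[cbind(idx_plot, idx_year)],
    instrument = Z[cbind(idx_plot, idx_year)],
    cov_plot = cov_plot_obs[idx_plot],
    cov_siteyear = cov_sy_obs[sy_index(site_of_plot[idx_plot], idx_year)],
    stringsAsFactors = FALSE)
  if (by_type) {
    for (k in seq_len(4L)) {
      panel[[paste0("R_", names(config$beta_by_type)[k])]] <-
        Rk[cbind(idx_plot, idx_year, k)]
    }
  }
  panel <- build_panel(panel, inclusion_min_years = min(5L, T))

  truth <- list(
    config = config,
    plot_loadings = data.frame(plot_tab, alpha = plot_load[, "r"],
                               delta = plot_load[, "p"]),
    siteyear_loadings = data.frame(
      site_id = rep(site_id, each = T), year = 2000L + rep(seq_len(T), S),
      nu = sy_load[, "r"], mu = sy_load[, "p"]),
    latent = data.frame(
      site_id = plot_tab$site_id[idx_plot],
      plot_id = plot_tab$plot_id[idx_plot],
      year = 2000L + idx_year,
      ln_richness_latent = lnR_lat[cbind(idx_plot, idx_year)],
      ln_biomass_latent = lnP_lat[cbind(idx_plot, idx_year)],
      plotyear_r = py_load[(idx_plot - 1L) * T + idx_year, "r"],
      plotyear_p = py_load[(idx_plot - 1L) * T + idx_year, "p"]))

  out <- list(panel = panel, truth = truth)
  if (by_type) {
    cover <- do.call(rbind, cover_rows)
    rownames(cover) <- NULL
    out$cover <- cover
    out$pool <- pool
  }
  out
}

# Per-site species pool with geometric rank abundance. A species' true
# relative abundance is decay^rank renormalized over the pool; it is rare
# iff that abundance is below rarity_cutoff; origin is an independent
# Bernoulli(frac_nonnative) draw, fixed per species per site.
simulate_species_pool <- function(config) {
  lapply(seq_len(config$n_sites), function(s) {
    k <- seq_len(config$pool_size)
    ab <- config$rank_abundance_decay^k
    ab <- ab / sum(ab)
    origin <- ifelse(stats::runif(config$pool_size) < config$frac_nonnative,
                     "non-native", "native")
    rare <- ab < config$rarity_cutoff
    type <- paste0(ifelse(rare, "rare_", "nonrare_"),
                   ifelse(origin == "native", "native", "nonnative"))
    data.frame(species_id = sprintf("site%02d_sp%03d", s, k),
               rank = k, abundance = ab, origin = origin, rare = rare,
               type = factor(type, levels = c("rare_native", "nonrare_native",
                                              "nonrare_nonnative",
                                              "rare_nonnative")),
               stringsAsFactors = FALSE)
  })
}

# Draw the community of a single plot-year: R species sampled without
# replacement with probability proportional to pool abundance (so the
# first species drawn tend to be dominant and the marginal species added
# at higher richness tend to be rare), covers proportional to pool
# abundance times lognormal noise, renormalized to sum to 1.
draw_community <- function(pool_site, R) {
  if (R > nrow(pool_site)) stop("requested richness exceeds species pool")
  idx <- sample.int(nrow(pool_site), R, prob = pool_site$abundance)
  w <- pool_site$abundance[idx] * exp(stats::rnorm(R, sd = 0.4))
  counts <- integer(4L)
  tab <- tabulate(as.integer(pool_site$type[idx]), nbins = 4L)
  list(species_id = pool_site$species_id[idx],
       relative_cover = w / sum(w),
       origin = pool_site$origin[idx],
       type_counts = tab)
}

#' Simulate species cover for given plot-year richness values
#'
#' Builds per-site species pools with geometric rank abundance and draws,
#' for every plot-year row of `richness_df`, a community of the requested
#' richness: species are sampled without replacement with probability
#' proportional to their pool abundance, so the incremental species
#' present at higher richness are increasingly likely to be rare (and,
#' when origin is random across ranks, non-native). Relative covers are
#' the pool abundances perturbed by lognormal noise and renormalized to
#' sum to one within the plot-year.
#'
#' @param config A [sim_config()]; `pool_size`, `rank_abundance_decay`,
#'   `frac_nonnative`, `rarity_cutoff` and `seed` are used.
#' @param richness_df Data frame with `site_id`, `plot_id`, `year`,
#'   `richness`; `site_id` must take at most `config$n_sites` distinct
#'   values.
#' @return List with `cover` (long cover table: `site_id`, `plot_id`,
#'   `year`, `species_id`, `relative_cover`, `origin`) and `pool` (list of
#'   per-site pool tables with the true abundances and types).
#' @export
simulate_cover <- function(config, richness_df) {
  stopifnot(inherits(config, "sim_config"))
  richness_df <- as.data.frame(richness_df)
  stopifnot(all(c("site_id", "plot_id", "year", "richness") %in% names(richness_df)))
  if (any(richness_df$richness > config$pool_size)) {
    stop("requested richness exceeds pool_size")
  }
  sites <- sort(unique(richness_df$site_id))
  if (length(sites) > config$n_sites) {
    stop("more sites in richness_df than config$n_sites")
  }
  set.seed(config$seed + 1L)   # separate stream from simulate_panel()
  pool <- simulate_species_pool(config)
  site_idx <- match(richness_df$site_id, sites)
  rows <- vector("list", nrow(richness_df))
  for (i in seq_len(nrow(richness_df))) {
    draw <- draw_community(pool[[site_idx[i]]], richness_df$richness[i])
    rows[[i]] <- data.frame(site_id = richness_df$site_id[i],
                            plot_id = richness_df$plot_id[i],
                            year = richness_df$year[i],
                            species_id = draw$species_id,
                            relative_cover = draw$relative_cover,
                            origin = draw$origin,
                            stringsAsFactors = FALSE)
  }
  cover <- do.call(rbind, rows)
  rownames(cover) <- NULL
  list(cover = cover, pool = pool)
}
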