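test_that("identical config and seed reproduce the panel bit for bit", {
  cfg <- sim_scenario("paper_like", seed = 123, n_sites = 6L)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(as.data.frame(a$panel), as.data.frame(b$panel))
  expect_identical(a$truth$latent, b$truth$latent)
  c2 <- simulate_panel(sim_scenario("paper_like", seed = 124, n_sites = 6L))
  expect_false(identical(a$panel$live_mass, c2$panel$live_mass))
})

test_that("noiseless generation returns the elasticity exactly", {
  cfg <- sim_config(n_sites = 6L, plots_per_site = 3L, n_years = 6L,
                    beta_true = -0.24,
                    sd_plot_confounder = 0, sd_siteyear_confounder = 0,
                    sd_plotyear_confounder = 0, reverse_lambda = 0,
                    sd_noise = 0, instrument_strength = 0, seed = 4)
  p <- simulate_panel(cfg)$panel
  slope <- coef(lm(log(live_mass) ~ log(richness), data = p))[[2]]
  expect_equal(slope, -0.24, tolerance = 1e-10)
})

test_that("pooled-OLS bias equals the omitted-variable-bias formula on realized draws", {
  cfg <- sim_config(n_sites = 30L, plots_per_site = 4L, n_years = 8L,
                    sd_plot_confounder = 0, sd_siteyear_confounder = 0.3,
                    rho_siteyear = 0.8, sd_plotyear_confounder = 0,
                    reverse_lambda = 0, instrument_strength = 0, seed = 31)
  sim <- simulate_panel(cfg)
  p <- as.data.frame(sim$panel)
  lnR <- log(p$richness)
  lnP <- log(p$live_mass)
  # realized site-year biomass loadings, matched to rows
  sy <- sim$truth$siteyear_loadings
  mu <- sy$mu[match(paste(p$site_id, p$year), paste(sy$site_id, sy$year))]
  slope <- coef(lm(lnP ~ lnR))[[2]]
  ovb_mu <- cov(lnR, mu) / var(lnR)
  # the only other error component is the iid biomass noise
  eps <- lnP - cfg$beta_true * lnR - cfg$mean_log_biomass - mu
  ovb_full <- cov(lnR, mu + eps) / var(lnR)
  # exact algebraic identity on the draws
  expect_equal(slope, cfg$beta_true + ovb_full, tolerance = 1e-10)
  # the confounder term dominates and has the sign of rho_siteyear
  expect_gt(ovb_mu, 0)
  expect_equal(slope, cfg$beta_true + ovb_mu, tolerance = 0.06)
})

test_that("a valid instrument is uncorrelated with the biomass error", {
  cfg <- sim_config(n_sites = 30L, plots_per_site = 4L, n_years = 8L,
                    instrument_strength = 0.3, reverse_lambda = 0, seed = 8)
  sim <- simulate_panel(cfg)
  p <- as.data.frame(sim$panel)
  # total structural biomass error (confounders + noise); exclusion means
  # the instrument is independent of it
  err <- log(p$live_mass) - cfg$beta_true * log(p$richness) -
    cfg$mean_log_biomass
  expect_lt(abs(cor(p$instrument, err)), 0.05)
})

test_that("single-species communities and cover normalization behave", {
  cfg <- sim_config(n_sites = 2L, seed = 6)
  rich <- data.frame(site_id = rep(c("sA", "sB"), each = 3),
                     plot_id = rep(c("p1", "p2"), each = 3),
                     year = rep(1:3, 2),
                     richness = c(1L, 5L, 12L, 1L, 20L, 7L))
  cov <- simulate_cover(cfg, rich)$cover
  one <- cov[cov$plot_id == "p1" & cov$year == 1, ]
  expect_equal(nrow(one), 1L)
  expect_equal(one$relative_cover, 1)
  sums <- tapply(cov$relative_cover,
                 interaction(cov$plot_id, cov$year, drop = TRUE), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_error(simulate_cover(cfg, transform(rich, richness = 1000L)),
               "pool_size")
})

test_that("the marginal species at higher richness is increasingly likely rare", {
  cfg <- sim_config(n_sites = 4L, seed = 12)
  # many plot-years across a wide richness ladder
  rich <- expand.grid(plot_id = sprintf("p%02d", 1:20), year = 1:10)
  rich$site_id <- rep(sprintf("sA%d", 1:4), each = 5)[match(rich$plot_id,
                                                            sprintf("p%02d", 1:20))]
  set.seed(99)
  rich$richness <- sample(2:35, nrow(rich), replace = TRUE)
  out <- simulate_cover(cfg, rich)
  cov <- out$cover
  pool <- out$pool
  # brute-force tabulation: per community, is its rarest-by-pool-abundance
  # member (the marginal addition) a rare species?
  rare_of <- do.call(rbind, pool)
  key <- rare_of$species_id
  ab <- setNames(rare_of$abundance, key)
  rare <- setNames(rare_of$rare, key)
  g <- split(cov, interaction(cov$plot_id, cov$year, drop = TRUE))
  marg <- vapply(g, function(d) {
    i <- which.min(ab[d$species_id])
    c(R = nrow(d), rare = as.numeric(rare[d$species_id[i]]))
  }, numeric(2))
  R <- marg["R", ]; is_rare <- marg["rare", ]
  lo <- mean(is_rare[R <= 10]); hi <- mean(is_rare[R >= 20])
  expect_gt(hi, lo)
  # and the trend is monotone-ish in richness (positive slope)
  expect_gt(coef(lm(is_rare ~ R))[[2]], 0)
})

test_that("per-type counts from the typed simulation partition richness", {
  sim <- simulate_panel(sim_scenario("confounded", seed = 13), by_type = TRUE)
  p <- as.data.frame(sim$panel)
  rk <- p[, grep("^R_", names(p))]
  expect_true(all(rowSums(rk) == p$richness))
  # cover table agrees with the panel's richness
  n_sp <- tapply(sim$cover$species_id,
                 interaction(sim$cover$plot_id, sim$cover$year, drop = TRUE),
                 length)
  expect_setequal(as.integer(n_sp), unique(p$richness))
})

test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(rho_plot = 1.5), "correlations")
  expect_error(sim_config(sd_noise = -1), "non-negative")
  expect_error(sim_config(rank_abundance_decay = 1), "rank_abundance_decay")
  expect_error(sim_config(n_sites = 0), "positive")
  expect_error(sim_config(rarity_cutoff = 0), "rarity_cutoff")
})
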