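test_that("the within estimate equals explicit-dummy least squares", {
  for (s in 1:6) {
    raw <- random_raw_panel(n_sites = 3, plots_per_site = 2, n_years = 3,
                            seed = s)
    panel <- build_panel(raw, inclusion_min_years = 3)
    fit <- estimate_main_design(panel)
    oracle <- lm_dummy_beta(panel)
    expect_equal(beta_richness(fit), coef(oracle)[["lnR"]],
                 tolerance = 1e-8)
  }
})

test_that("noiseless fixed-effects panel is identified exactly", {
  # arbitrary plot effects and site-year shocks, zero noise
  set.seed(77)
  g <- expand.grid(plot = 1:6, year = 1:4)
  g$site <- (g$plot - 1) %/% 2 + 1
  d_p <- rnorm(6, sd = 1)
  m_st <- matrix(rnorm(12, sd = 0.8), 3, 4)
  R <- sample(2:20, nrow(g), replace = TRUE)
  lnP <- -0.24 * log(R) + d_p[g$plot] + m_st[cbind(g$site, g$year)]
  panel <- build_panel(data.frame(
    site_id = paste0("s", g$site), plot_id = paste0("p", g$plot),
    year = g$year, live_mass = exp(lnP), richness = R),
    inclusion_min_years = 4)
  expect_equal(beta_richness(estimate_main_design(panel)), -0.24,
               tolerance = 1e-10)
})

test_that("bivariate design is self-consistent with the least-squares core", {
  p <- simulate_panel(sim_scenario("confounded", seed = 2))$panel
  f <- estimate_bivariate(p)
  direct <- ols_fit(log(p$live_mass),
                    cbind(`(Intercept)` = 1, ln_richness = log(p$richness)))
  expect_equal(beta_richness(f), direct$coefficients[["ln_richness"]],
               tolerance = 1e-12)
})

test_that("orthogonal covariates leave the common-design slope at the bivariate value", {
  set.seed(14)
  p <- simulate_panel(sim_scenario("confounded", seed = 2))$panel
  p2 <- as.data.frame(p)
  lnR <- log(p2$richness)
  z <- rnorm(nrow(p2))
  p2$orth <- resid(lm(z ~ lnR))          # exactly orthogonal to ln richness
  p2 <- build_panel(p2)
  f_common <- estimate_common_design(p2, "orth")
  f_biv <- estimate_bivariate(p2)
  expect_equal(beta_richness(f_common), beta_richness(f_biv),
               tolerance = 1e-10)
})

test_that("perfectly measured confounders restore the truth in the common design", {
  cfg <- sim_scenario("confounded", seed = 20, sd_covariate_noise = 0,
                      n_sites = 25L, n_years = 8L)
  p <- simulate_panel(cfg)$panel
  f <- estimate_common_design(p, c("cov_plot", "cov_siteyear"))
  expect_equal(beta_richness(f), cfg$beta_true, tolerance = 0.05)
})

test_that("a time-invariant plot covariate does not move the within estimate", {
  p <- as.data.frame(simulate_panel(sim_scenario("confounded", seed = 9))$panel)
  p$plot_constant <- ave(rnorm(nrow(p)), p$plot_id)   # constant within plot
  p <- build_panel(p)
  base <- estimate_main_design(p)
  expect_warning(with_cov <- estimate_main_design(p, extra_covariates = "plot_constant"),
                 "absorbed")
  expect_equal(beta_richness(with_cov), beta_richness(base), tolerance = 1e-8)
})

test_that("first differences equal the within estimator on a two-year panel", {
  raw <- random_raw_panel(n_sites = 4, plots_per_site = 3, n_years = 2,
                          seed = 33)
  panel <- build_panel(raw, inclusion_min_years = 2)
  fit <- estimate_main_design(panel)
  d <- as.data.frame(panel)
  d <- d[order(d$plot_id, d$year), ]
  second <- duplicated(d$plot_id)
  dy <- diff(log(d$live_mass))[second[-1]]
  dx <- diff(log(d$richness))[second[-1]]
  site <- factor(d$site_id[second])
  fd <- coef(lm(dy ~ dx + site))[["dx"]]
  expect_equal(beta_richness(fit), fd, tolerance = 1e-10)
})

test_that("degenerate designs raise informative errors", {
  p <- simulate_panel(sim_scenario("confounded", seed = 3))$panel
  # constant richness: no identifying variation under two-way FE
  p2 <- as.data.frame(p)
  p2$richness <- 7L
  p2 <- build_panel(p2)
  expect_error(estimate_main_design(p2), "no identifying variation")
  expect_error(estimate_common_design(p, "not_a_column"), "not_a_column")
})

test_that("moderation: null interaction is near zero and main effect is refused", {
  p <- as.data.frame(simulate_panel(sim_scenario("confounded", seed = 17,
                                                 n_sites = 20L))$panel)
  site_mean <- tapply(log(p$live_mass), p$site_id, mean)
  p$site_prod <- site_mean[p$site_id]
  p <- build_panel(p)
  expect_error(estimate_moderation(p, "site_prod", include_main_effect = TRUE),
               "collinear")
  f <- estimate_moderation(p, "site_prod", coding = "continuous")
  i <- grep(":", f$coefficients$term)
  # homogeneous-effect DGP: interaction is a null effect
  expect_lt(abs(f$coefficients$statistic[i]), 3)
  expect_gt(f$joint_test$p_value, 0.001)
})

test_that("moderation recovers a two-fold effect difference across site groups", {
  # build a panel whose elasticity differs by site group
  set.seed(55)
  g <- expand.grid(plot = 1:40, year = 1:8)
  g$site <- (g$plot - 1) %/% 4 + 1
  hi <- g$site > 5
  beta <- ifelse(hi, -0.5, -0.2)
  R <- pmax(1L, round(exp(rnorm(nrow(g), 2.2, 0.4))))
  lnP <- beta * log(R) + rep(rnorm(40, sd = 0.4), times = 8)[g$plot] +
    rnorm(nrow(g), sd = 0.15)
  p <- build_panel(data.frame(
    site_id = paste0("s", g$site), plot_id = paste0("p", g$plot),
    year = g$year, live_mass = exp(lnP), richness = R,
    high_group = ifelse(g$site > 5, "high", "low")), inclusion_min_years = 5)
  f <- estimate_moderation(p, "high_group", coding = "categorical")
  i <- grep("high_group", f$coefficients$term)
  # equals the explicit-dummy oracle with the interaction term
  d <- as.data.frame(p)
  d$lnR <- log(d$richness); d$lnP <- log(d$live_mass)
  oracle <- lm(lnP ~ lnR + lnR:high_group + factor(plot_id) +
                 droplevels(interaction(site_id, year)), data = d)
  expect_equal(f$coefficients$estimate[i], coef(oracle)[["lnR:high_grouplow"]],
               tolerance = 1e-8)
  # "high" sites (beta -0.5) are the reference level; the "low" (-0.2)
  # interaction approximates +0.3
  expect_lt(abs(f$coefficients$estimate[i] - 0.3), 0.12)
  expect_lt(f$joint_test$p_value, 0.05)
})
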