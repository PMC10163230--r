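test_that("two-species classification splits at the cutoff", {
  cov <- data.frame(site_id = "s1",
                    plot_id = rep(c("p1", "p2"), each = 2),
                    year = 2001,
                    species_id = rep(c("dom", "rare"), 2),
                    relative_cover = rep(c(0.9, 0.1), 2),
                    origin = rep(c("native", "non-native"), 2),
                    stringsAsFactors = FALSE)
  tt <- classify_species(cov, cutoff = 0.2)
  expect_equal(tt$rare[tt$species_id == "dom"], FALSE)
  expect_equal(tt$rare[tt$species_id == "rare"], TRUE)
  expect_equal(as.character(tt$type[tt$species_id == "dom"]), "nonrare_native")
  expect_equal(as.character(tt$type[tt$species_id == "rare"]), "rare_nonnative")
})

test_that("raising the cutoff never reclassifies rare back to non-rare", {
  sim <- simulate_panel(sim_scenario("confounded", seed = 31), by_type = TRUE)
  cuts <- c(0.02, 0.05, 0.1, 0.2)
  tabs <- lapply(cuts, function(ct) classify_species(sim$cover, cutoff = ct))
  for (i in seq_len(length(cuts) - 1)) {
    a <- tabs[[i]]; b <- tabs[[i + 1]]
    key <- paste(a$site_id, a$species_id)
    m <- match(key, paste(b$site_id, b$species_id))
    expect_true(all(!a$rare | b$rare[m]))   # rare stays rare as cutoff grows
  }
})

test_that("rare fraction in a geometric pool matches rank tabulation", {
  cfg <- sim_config(n_sites = 3L, pool_size = 50L,
                    rank_abundance_decay = 0.8, rarity_cutoff = 0.05,
                    seed = 17)
  pool <- simulate_panel(cfg, by_type = TRUE)$pool
  for (pl in pool) {
    # brute force: renormalized geometric series, ranks whose share < cutoff
    ab <- 0.8^seq_len(50); ab <- ab / sum(ab)
    expect_equal(pl$abundance, ab, tolerance = 1e-12)
    expect_identical(pl$rare, ab < 0.05)
  }
})

test_that("per-type richness partitions total richness on a hand-built toy", {
  cov <- rbind(
    data.frame(site_id = "s1", plot_id = "p1", year = 2001,
               species_id = c("a", "b", "c", "d", "e"),
               relative_cover = c(0.4, 0.3, 0.15, 0.1, 0.05),
               origin = c("native", "native", "non-native", "native", "non-native")),
    data.frame(site_id = "s1", plot_id = "p1", year = 2002,
               species_id = c("a", "b"),
               relative_cover = c(0.7, 0.3),
               origin = c("native", "native")))
  tt <- classify_species(cov, cutoff = 0.1)
  # site abundance averages over the two plot-years (absence = 0):
  # a: .55, b: .30, c: .075, d: .05, e: .025 -> c, d, e rare
  expect_setequal(tt$species_id[tt$rare], c("c", "d", "e"))
  rk <- per_type_richness(cov, tt)
  expect_equal(rk$richness, c(5L, 2L))
  y1 <- rk[rk$year == 2001, ]
  expect_equal(y1$R_nonrare_native, 2L)      # a, b
  expect_equal(y1$R_rare_native, 1L)         # d
  expect_equal(y1$R_rare_nonnative, 2L)      # c, e
  expect_equal(y1$R_nonrare_nonnative, 0L)
  expect_true(all(rowSums(rk[, grep("^R_", names(rk))]) == rk$richness))
})

test_that("noiseless per-type simulation is recovered exactly", {
  cfg <- sim_config(n_sites = 8L, plots_per_site = 3L, n_years = 6L,
                    sd_plot_confounder = 0, sd_siteyear_confounder = 0,
                    sd_plotyear_confounder = 0, sd_noise = 0,
                    reverse_lambda = 0, instrument_strength = 0,
                    beta_by_type = c(rare_native = -0.06,
                                     nonrare_native = 0.09,
                                     nonrare_nonnative = -0.07,
                                     rare_nonnative = -0.02),
                    seed = 23)
  sim <- simulate_panel(cfg, by_type = TRUE)
  fit <- estimate_by_type(sim$panel)
  est <- fit$coefficients$estimate
  names(est) <- sub("^ihs_R_", "", fit$coefficients$term)
  expect_equal(est[names(cfg$beta_by_type)], cfg$beta_by_type,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("per-type signs are recovered under confounding", {
  cfg <- sim_scenario("confounded", seed = 29, n_sites = 25L, n_years = 8L)
  sim <- simulate_panel(cfg, by_type = TRUE)
  fit <- estimate_by_type(sim$panel)
  est <- fit$coefficients$estimate
  names(est) <- sub("^ihs_R_", "", fit$coefficients$term)
  expect_equal(sign(est[names(cfg$beta_by_type)]),
               sign(cfg$beta_by_type), ignore_attr = TRUE)
})

test_that("the equality statistic is zero for identical coefficients and base-invariant", {
  fit <- list(coefficients = data.frame(
    term = paste0("ihs_R_", c("rare_native", "nonrare_native",
                              "nonrare_nonnative", "rare_nonnative")),
    estimate = rep(-0.05, 4)),
    vcov = diag(4) * 0.01 + 0.002)
  out <- equality_test(fit)
  expect_equal(out$statistic, 0, tolerance = 1e-12)
  expect_equal(out$p_value, 1)

  sim <- simulate_panel(sim_scenario("confounded", seed = 35), by_type = TRUE)
  f <- estimate_by_type(sim$panel)
  stats <- vapply(1:4, function(b) equality_test(f, base = b)$statistic,
                  numeric(1))
  expect_equal(max(stats) - min(stats), 0, tolerance = 1e-8)
})

test_that("classification is deterministic and respects the metric choice", {
  sim <- simulate_panel(sim_scenario("confounded", seed = 31), by_type = TRUE)
  t1 <- classify_species(sim$cover, cutoff = 0.05)
  t2 <- classify_species(sim$cover, cutoff = 0.05)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  tf <- classify_species(sim$cover, cutoff = 0.5,
                         metric = "relative_frequency")
  expect_true(is.numeric(tf$abundance))
  expect_true(all(tf$abundance <= 1 + 1e-12))
})
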