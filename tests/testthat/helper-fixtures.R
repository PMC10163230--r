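# Small deterministic fixtures shared across tests. Everything is built
# in code; no files.

# A raw long table with arbitrary plot/site-year structure and known
# effects, for oracle comparisons against explicit-dummy least squares.
random_raw_panel <- function(n_sites = 3, plots_per_site = 2, n_years = 3,
                             beta = -0.24, seed = 1) {
  set.seed(seed)
  g <- expand.grid(plot = seq_len(n_sites * plots_per_site),
                   year = seq_len(n_years))
  g$site <- (g$plot - 1) %/% plots_per_site + 1
  d_p <- rnorm(n_sites * plots_per_site, sd = 0.5)
  m_st <- matrix(rnorm(n_sites * n_years, sd = 0.4), n_sites, n_years)
  lnR <- log(pmax(1, round(exp(rnorm(nrow(g), mean = 2, sd = 0.4)))))
  lnP <- beta * lnR + d_p[g$plot] + m_st[cbind(g$site, g$year)] +
    rnorm(nrow(g), sd = 0.3)
  data.frame(site_id = paste0("s", g$site),
             plot_id = paste0("p", g$plot),
             year = 2000 + g$year,
             live_mass = exp(lnP),
             richness = as.integer(round(exp(lnR))),
             stringsAsFactors = FALSE)
}

# Dummy-regression oracle: the within estimate via lm() with explicit
# plot and site-year indicator columns.
lm_dummy_beta <- function(panel, extra = NULL) {
  d <- as.data.frame(panel)
  d$lnP <- log(d$live_mass)
  d$lnR <- log(d$richness)
  d$pl <- factor(d$plot_id)
  d$sy <- droplevels(interaction(d$site_id, d$year))
  rhs <- "lnR + pl + sy"
  if (!is.null(extra)) rhs <- paste(paste(extra, collapse = " + "), "+", rhs)
  fit <- lm(stats::as.formula(paste("lnP ~", rhs)), data = d)
  fit
}

# Construct an exactly model-consistent instance of the proportional-
# selection framework: y = beta*x + w1 + w2 + e with cov(w1, w2) = 0.
# All regression moments are then computed from data, giving an oracle
# in which the correct bias adjustment is known by construction.
make_oster_instance <- function(beta = -0.3, delta_true = 0.6, n = 2e5,
                                seed = 1) {
  set.seed(seed)
  w1 <- rnorm(n, sd = 1.2)
  w2 <- rnorm(n, sd = 0.8)
  # x correlated with both indices, with selection ratio delta_true:
  # cov(x,w2)/var(w2) = delta_true * cov(x,w1)/var(w1)
  a1 <- 0.5
  a2 <- delta_true * a1
  x <- a1 * w1 + a2 * w2 + rnorm(n, sd = 1)
  e <- rnorm(n, sd = 0.7)
  y <- beta * x + w1 + w2 + e
  short <- lm(y ~ x)
  ctrl <- lm(y ~ x + w1)
  r2 <- function(m) summary(m)$r.squared
  full <- lm(y ~ x + w1 + w2)
  list(inputs = oster_inputs(
         beta_dot = coef(short)[["x"]], r2_dot = r2(short),
         beta_tilde = coef(ctrl)[["x"]], r2_tilde = r2(ctrl),
         pi = delta_true, r_max = r2(full),
         var_y = var(y), var_x = var(x),
         var_x_resid = var(resid(lm(x ~ w1)))),
       beta = beta)
}
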