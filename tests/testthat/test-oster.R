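test_that("pi = 0 and r_max = r2_tilde leave the coefficient untouched", {
  base <- oster_inputs(beta_dot = 0.10, r2_dot = 0.02,
                       beta_tilde = -0.20, r2_tilde = 0.60,
                       pi = 0, r_max = 1,
                       var_y = 1.5, var_x = 0.9, var_x_resid = 0.5)
  for (m in c("approximation", "exact_root")) {
    expect_equal(oster_adjusted_beta(base, m)$beta_adjusted, -0.20,
                 tolerance = 1e-10)
  }
  at_rtilde <- oster_inputs(beta_dot = 0.10, r2_dot = 0.02,
                            beta_tilde = -0.20, r2_tilde = 0.60,
                            pi = -0.10, r_max = 0.60,
                            var_y = 1.5, var_x = 0.9, var_x_resid = 0.5)
  for (m in c("approximation", "exact_root")) {
    expect_equal(oster_adjusted_beta(at_rtilde, m)$beta_adjusted, -0.20,
                 tolerance = 1e-10)
  }
})

test_that("the exact root recovers the true coefficient on a model-consistent instance", {
  inst <- make_oster_instance(beta = -0.3, delta_true = 0.6, seed = 2)
  out <- oster_adjusted_beta(inst$inputs, "exact_root")
  expect_equal(out$beta_adjusted, inst$beta, tolerance = 0.02)
})

test_that("cubic roots match a brute-force grid search oracle", {
  inst <- make_oster_instance(beta = -0.3, delta_true = 0.8, seed = 3)
  inp <- inst$inputs
  out <- oster_adjusted_beta(inp, "exact_root")
  # independent evaluation of the cubic over a grid of candidate biases
  d2 <- inp$beta_dot - inp$beta_tilde
  d3 <- (inp$r2_tilde - inp$r2_dot) * inp$var_y
  d4 <- (inp$r_max - inp$r2_tilde) * inp$var_y
  tau <- inp$var_x_resid; sx <- inp$var_x; dl <- inp$pi
  f <- function(nu) {
    -tau * (dl - 1) * (sx - tau) * nu^3 - d2 * sx * tau * (dl - 2) * nu^2 +
      (d2^2 * sx * tau + d3 * tau - d4 * dl * (sx - tau)) * nu -
      d2 * d4 * dl * sx
  }
  span <- max(3, 2 * max(abs(inp$beta_tilde - out$roots)))
  grid <- seq(-span, span, by = 1e-4)
  vals <- f(grid)
  flips <- which(diff(sign(vals)) != 0)
  roots_grid <- vapply(flips, function(i) {
    uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-12)$root
  }, numeric(1))
  nus <- inp$beta_tilde - out$roots
  for (nu in nus) {
    expect_lt(min(abs(roots_grid - nu)), 1e-6)
  }
  # selection rule: smallest bias among the real roots
  expect_equal(out$beta_adjusted,
               inp$beta_tilde - roots_grid[which.min(abs(roots_grid))],
               tolerance = 1e-6)
})

test_that("approximation and exact root agree to first order in pi", {
  inst <- make_oster_instance(beta = -0.3, delta_true = 0.5, seed = 4)
  inp <- inst$inputs
  devs <- vapply(c(0.05, 0.025, 0.0125), function(p) {
    inp$pi <- p
    a <- oster_adjusted_beta(inp, "approximation")$beta_adjusted
    e <- oster_adjusted_beta(inp, "exact_root")$beta_adjusted
    abs(a - e)
  }, numeric(1))
  # difference shrinks faster than pi itself (second order)
  expect_lt(devs[2], devs[1] / 1.8)
  expect_lt(devs[3], devs[2] / 1.8)
})

test_that("the adjusted coefficient is monotone in pi and in r_max", {
  inst <- make_oster_instance(beta = -0.3, delta_true = 0.6, seed = 5)
  inp <- inst$inputs
  by_pi <- vapply(seq(0, 0.6, by = 0.1), function(p) {
    inp$pi <- p
    oster_adjusted_beta(inp, "exact_root")$beta_adjusted
  }, numeric(1))
  # beta_dot > beta_tilde here, so stronger selection pushes beta* down
  dir <- sign(inp$beta_dot - inp$beta_tilde)
  expect_true(all(dir * diff(by_pi) < 0))
  by_rmax <- vapply(seq(inp$r2_tilde + 0.02, 1, length.out = 6), function(r) {
    inp2 <- inp
    inp2$pi <- 0.3
    inp2$r_max <- r
    oster_adjusted_beta(inp2, "exact_root")$beta_adjusted
  }, numeric(1))
  expect_true(all(dir * diff(by_rmax) < 0))
})

test_that("input validation enforces the R-squared ordering", {
  expect_error(oster_inputs(0.1, 0.5, 0.2, 0.3, -0.1, 1), "r2_dot")
  expect_error(
    oster_adjusted_beta(oster_inputs(0.1, 0.1, 0.2, 0.1, -0.1, 1),
                        "approximation"),
    "division by zero")
})
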