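#' Inputs for the proportional-selection sensitivity bound
#'
#' Collects the moments needed for the omitted-variable-bias bound of the
#' Altonji/Oster proportional-selection framework: the treatment
#' coefficient and R-squared from the uncontrolled ("short") regression
#' and from the controlled regression, the proportional-selection
#' coefficient `pi` (how strongly unobservables select on treatment
#' relative to the observables; negative values posit a confounder
#' pushing richness and productivity in opposite directions), and the
#' maximum attainable R-squared `r_max`.
#'
#' The first-order approximation needs only these six numbers. The exact
#' (cubic-root) solution additionally needs three second moments of the
#' data: the outcome variance, the treatment variance, and the residual
#' variance of the treatment after projection on the controls. When the
#' inputs are built from two fitted designs via [oster_inputs_from_fits()]
#' these are filled automatically.
#'
#' @param beta_dot,r2_dot Coefficient and R-squared of the uncontrolled
#'   regression.
#' @param beta_tilde,r2_tilde Coefficient and R-squared of the controlled
#'   regression.
#' @param pi Proportional selection coefficient.
#' @param r_max Maximum R-squared, in `(r2_tilde, 1]`.
#' @param var_y,var_x,var_x_resid Optional second moments (outcome
#'   variance, treatment variance, residual treatment variance after
#'   controls) required by the exact method.
#' @return An `oster_inputs` object.
#' @export
oster_inputs <- function(beta_dot, r2_dot, beta_tilde, r2_tilde,
                         pi = -0.10, r_max = 1,
                         var_y = NULL, var_x = NULL, var_x_resid = NULL) {
  if (!(r2_dot <= r2_tilde && r2_tilde <= r_max && r_max <= 1)) {
    stop("need r2_dot <= r2_tilde <= r_max <= 1")
  }
  structure(list(beta_dot = beta_dot, r2_dot = r2_dot,
                 beta_tilde = beta_tilde, r2_tilde = r2_tilde,
                 pi = pi, r_max = r_max,
                 var_y = var_y, var_x = var_x, var_x_resid = var_x_resid),
            class = "oster_inputs")
}

#' Build sensitivity inputs from an uncontrolled and a controlled fit
#'
#' Uses the bivariate design as the short regression and the two-way
#' fixed-effects (or covariate-adjusted) design as the controlled
#' regression. The controlled R-squared is the total R-squared including
#' the absorbed fixed effects, since those are the "observables" whose
#' explanatory power the proportional-selection assumption scales
#' against. The residual treatment variance is the within variance of
#' ln richness after fixed-effect absorption.
#'
#' @param fit_short A `bef_fit` from [estimate_bivariate()].
#' @param fit_controlled A `bef_fit` from [estimate_main_design()] (or
#'   [estimate_common_design()]).
#' @param panel The panel both fits were estimated on.
#' @param pi,r_max See [oster_inputs()].
#' @return An `oster_inputs` object with all second moments filled.
#' @export
oster_inputs_from_fits <- function(fit_short, fit_controlled, panel,
                                   pi = -0.10, r_max = 1) {
  y <- log(panel$live_mass)
  x <- log(panel$richness)
  if (length(fit_controlled$fixed_effects)) {
    fe <- fe_factors(panel, fe_spec(
      plot = "plot" %in% fit_controlled$fixed_effects,
      site_year = "site_year" %in% fit_controlled$fixed_effects))
    xt <- absorb_fixed_effects(cbind(x), fe)$x[, 1L]
  } else {
    xt <- stats::residuals(stats::lm(x ~ 1))
  }
  oster_inputs(beta_dot = beta_richness(fit_short),
               r2_dot = fit_short$r2_total,
               beta_tilde = beta_richness(fit_controlled),
               r2_tilde = fit_controlled$r2_total,
               pi = pi, r_max = r_max,
               var_y = stats::var(y), var_x = stats::var(x),
               var_x_resid = sum(xt^2) / (length(xt) - 1L))
}

#' Bias-adjusted coefficient under proportional selection
#'
#' Computes the bound on the treatment coefficient if an unobserved
#' confounder selected on treatment `pi` times as strongly as the
#' observables and the full model attained R-squared `r_max`.
#'
#' Two methods are provided. `"approximation"` is the widely used
#' first-order formula
#' `beta* = beta_tilde - pi * (beta_dot - beta_tilde) * (r_max - r2_tilde) / (r2_tilde - r2_dot)`.
#' `"exact_root"` solves the cubic in the bias `nu = beta_tilde - beta*`
#' implied by the single-index proportional-selection model's moment
#' conditions,
#' \deqn{-\tau(\pi-1)(\sigma_x^2-\tau)\,\nu^3
#'       - d_2\sigma_x^2\tau(\pi-2)\,\nu^2
#'       + (d_2^2\sigma_x^2\tau + d_3\tau - d_4\pi(\sigma_x^2-\tau))\,\nu
#'       - d_2 d_4 \pi \sigma_x^2 = 0,}
#' with \eqn{d_2 = \dot\beta - \tilde\beta},
#' \eqn{d_3 = (\tilde R - \dot R)\sigma_y^2},
#' \eqn{d_4 = (R_{max} - \tilde R)\sigma_y^2} and \eqn{\tau} the residual
#' treatment variance after controls; among real roots the one closest to
#' zero bias (adjusted coefficient closest to `beta_tilde`) is selected.
#' The two methods agree to first order in `pi`.
#'
#' @param inputs An [oster_inputs()] object.
#' @param method `"exact_root"` or `"approximation"`.
#' @return An `oster_result`: list with `beta_adjusted`, `method`,
#'   `identified_set` (sorted `c(beta_tilde, beta_adjusted)`), `pi`,
#'   `r_max`, and for the exact method `roots` (all real roots on the
#'   beta scale).
#' @export
oster_adjusted_beta <- function(inputs,
                                method = c("exact_root", "approximation")) {
  stopifnot(inherits(inputs, "oster_inputs"))
  method <- match.arg(method)
  with(inputs, {
    if (r2_tilde == r2_dot && method == "approximation") {
      stop("r2_tilde equals r2_dot: approximation undefined (division by zero)")
    }
    if (method == "approximation") {
      nu <- pi * (beta_dot - beta_tilde) * (r_max - r2_tilde) / (r2_tilde - r2_dot)
      beta_star <- beta_tilde - nu
      roots <- beta_star
    } else {
      if (is.null(var_y) || is.null(var_x) || is.null(var_x_resid)) {
        stop("exact_root needs var_y, var_x and var_x_resid ",
             "(see oster_inputs_from_fits())")
      }
      d2 <- beta_dot - beta_tilde
      d3 <- (r2_tilde - r2_dot) * var_y
      d4 <- (r_max - r2_tilde) * var_y
      tau <- var_x_resid
      sx <- var_x
      a3 <- -tau * (pi - 1) * (sx - tau)
      a2 <- -d2 * sx * tau * (pi - 2)
      a1 <- d2^2 * sx * tau + d3 * tau - d4 * pi * (sx - tau)
      a0 <- -d2 * d4 * pi * sx
      if (all(abs(c(a3, a2, a1)) < 1e-300)) stop("degenerate cubic")
      z <- polyroot(c(a0, a1, a2, a3))
      scale <- max(abs(z), 1)
      nu_real <- Re(z)[abs(Im(z)) < 1e-8 * scale]
      if (!length(nu_real)) stop("no real root of the sensitivity cubic")
      nu <- nu_real[which.min(abs(nu_real))]
      beta_star <- beta_tilde - nu
      roots <- beta_tilde - nu_real
    }
    structure(list(beta_adjusted = beta_star, method = method,
                   identified_set = sort(c(beta_tilde, beta_star)),
                   pi = pi, r_max = r_max, roots = roots,
                   beta_tilde = beta_tilde),
              class = "oster_result")
  })
}

#' @export
print.oster_result <- function(x, ...) {
  cat(sprintf("<oster_result> pi = %g, r_max = %g (%s)\n", x$pi, x$r_max, x$method))
  cat(sprintf("  beta_tilde = %.4f -> beta_adjusted = %.4f; identified set [%.4f, %.4f]\n",
              x$beta_tilde, x$beta_adjusted,
              x$identified_set[1], x$identified_set[2]))
  invisible(x)
}
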