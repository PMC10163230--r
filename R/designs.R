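#' @keywords internal
#' Fit a (possibly fixed-effects-absorbed) linear model with CR1 inference.
#' The workhorse behind every design: absorbs the requested factors from
#' the response and all regressors by alternating demeaning, solves least
#' squares, and computes the CR1 clustered sandwich with conservative
#' t-critical degrees of freedom (clusters - 1).
fit_design <- function(y, X, data, factors, cluster, design,
                       cluster_level, add_intercept = !length(factors),
                       conf_level = 0.95, tol = 1e-10) {
  keep <- stats::complete.cases(y, X, cluster)
  y <- y[keep]
  X <- X[keep, , drop = FALSE]
  cluster <- droplevels(as.factor(cluster[keep]))
  factors <- lapply(factors, function(f) droplevels(as.factor(f[keep])))
  n <- length(y)
  if (n < 3L) stop("too few usable observations (n = ", n, ")")

  if (add_intercept) X <- cbind(`(Intercept)` = 1, X)
  y_raw <- y
  df_abs <- 0L
  if (length(factors)) {
    ab <- absorb_fixed_effects(cbind(y, X), factors, tol = tol)
    y <- ab$x[, 1L]
    X <- ab$x[, -1L, drop = FALSE]
    df_abs <- fe_degrees_of_freedom(factors)
    # columns wiped out by absorption carry no identifying variation
    wiped <- apply(X, 2L, function(v) max(abs(v)) < sqrt(tol))
    if (all(wiped)) {
      stop("no identifying variation: all regressors are absorbed by the fixed effects")
    }
    if (any(wiped)) {
      warning("dropping regressor(s) absorbed by the fixed effects: ",
              paste(colnames(X)[wiped], collapse = ", "))
      X <- X[, !wiped, drop = FALSE]
    }
  }
  fit <- ols_fit(y, X)
  cr <- cluster_robust_vcov(fit, cluster, df_absorbed = df_abs)
  new_bef_fit(fit, cr, y, y_raw, design = design,
              cluster_level = cluster_level, df_absorbed = df_abs,
              fe = names(factors), conf_level = conf_level)
}

new_bef_fit <- function(fit, cr, y_within, y_raw, design, cluster_level,
                        df_absorbed, fe, conf_level = 0.95) {
  est <- fit$coefficients[fit$kept]
  se <- sqrt(diag(cr$vcov))
  dfree <- cr$n_clusters - 1L
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, dfree)
  tval <- est / se
  pval <- 2 * stats::pt(-abs(tval), dfree)
  rss <- sum(fit$residuals^2)
  tss_within <- sum((y_within - mean(y_within))^2)
  tss_raw <- sum((y_raw - mean(y_raw))^2)
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se),
                      conf_low = unname(est - tcrit * se),
                      conf_high = unname(est + tcrit * se),
                      statistic = unname(tval), p_value = unname(pval),
                      stringsAsFactors = FALSE)
  structure(list(design = design, coefficients = coefs, vcov = cr$vcov,
                 n_obs = fit$n, n_clusters = cr$n_clusters,
                 cluster_level = cluster_level, df = dfree,
                 fixed_effects = fe, df_absorbed = df_absorbed,
                 dropped = fit$dropped, conf_level = conf_level,
                 r2_within = 1 - rss / tss_within,
                 r2_total = 1 - rss / tss_raw,
                 residuals = fit$residuals, model = fit),
            class = "bef_fit")
}

#' @export
print.bef_fit <- function(x, ...) {
  cat(sprintf("<bef_fit> design: %s | n = %d, clusters (%s) = %d\n",
              x$design, x$n_obs, x$cluster_level, x$n_clusters))
  if (length(x$fixed_effects)) {
    cat("fixed effects:", paste(x$fixed_effects, collapse = " + "),
        sprintf("(%d absorbed df)\n", x$df_absorbed))
  }
  print(format(x$coefficients, digits = 4), row.names = FALSE)
  cat(sprintf("R2 within = %.4f, R2 total = %.4f\n", x$r2_within, x$r2_total))
  b <- beta_richness(x)
  if (!is.na(b)) {
    e <- elasticity_pct10(b)
    cat(sprintf("richness effect: %+.2f%% (linear) / %+.2f%% (exact) per +10%% richness\n",
                e[["pct_per_10pct_linear"]], e[["pct_per_10pct_exact"]]))
  }
  invisible(x)
}

#' Extract the richness coefficient from a fit
#'
#' @param fit A `bef_fit`.
#' @return The coefficient on the diversity regressor (`NA` if absent).
#' @export
beta_richness <- function(fit) {
  i <- match_diversity_term(fit$coefficients$term)
  if (is.na(i)) NA_real_ else fit$coefficients$estimate[i]
}

match_diversity_term <- function(terms) {
  cand <- c("ln_richness", "ln_simpson", "richness", "fitted_ln_richness")
  i <- which(terms %in% cand)
  if (length(i)) i[1L] else NA_integer_
}

#' Tidy coefficient table
#'
#' @param x A `bef_fit`.
#' @param ... Unused.
#' @return The coefficient data frame with the design label attached.
#' @export
tidy.bef_fit <- function(x, ...) {
  cbind(design = x$design, x$coefficients,
        n_obs = x$n_obs, n_clusters = x$n_clusters,
        stringsAsFactors = FALSE)
}

panel_cluster <- function(panel, level = c("plot", "site")) {
  level <- match.arg(level)
  if (level == "plot") interaction(panel$site_id, panel$plot_id, drop = TRUE)
  else factor(panel$site_id)
}

diversity_column <- function(panel, diversity_var) {
  switch(diversity_var,
    ln_richness = cbind(ln_richness = log(panel$richness)),
    ln_simpson = {
      if (!"simpson_d" %in% names(panel)) {
        stop("diversity_var = 'ln_simpson' needs a 'simpson_d' column")
      }
      cbind(ln_simpson = log(panel$simpson_d))
    },
    richness = cbind(richness = as.numeric(panel$richness)),
    richness_quadratic = cbind(richness = as.numeric(panel$richness),
                               richness_sq = as.numeric(panel$richness)^2),
    stop("unknown diversity_var: ", diversity_var))
}

#' Bivariate design: richness-productivity correlation
#'
#' Regresses ln biomass on ln richness with an intercept and no controls;
#' standard errors are clustered at the plot level. The slope is the
#' unadjusted richness-productivity elasticity and carries a causal
#' interpretation only under the (implausible) assumption of no
#' confounding at all.
#'
#' @param panel A `bef_panel`.
#' @param cluster_level `"plot"` (default) or `"site"`.
#' @return A `bef_fit`.
#' @export
estimate_bivariate <- function(panel, cluster_level = "plot") {
  fit_design(y = log(panel$live_mass),
             X = cbind(ln_richness = log(panel$richness)),
             data = panel, factors = list(),
             cluster = panel_cluster(panel, cluster_level),
             design = "bivariate", cluster_level = cluster_level)
}

#' Covariate-conditioning ("Common") design
#'
#' Regresses ln biomass on ln richness plus every listed covariate entered
#' directly (factors are expanded to indicator columns), mirroring the
#' conditioning-on-observables analyses common in observational ecology.
#' Rows with missing covariates are removed by listwise deletion; columns
#' collinear with earlier ones are dropped deterministically and reported.
#' Valid causal interpretation requires that the listed covariates capture
#' every confounder -- the strong assumption this design exists to
#' illustrate.
#'
#' @param panel A `bef_panel`.
#' @param covariates Character vector of column names in `panel`.
#' @param cluster_level `"plot"` (default) or `"site"`.
#' @return A `bef_fit`.
#' @export
estimate_common_design <- function(panel, covariates, cluster_level = "plot") {
  if (!length(covariates)) {
    stop("the covariate-conditioning design needs at least one covariate; ",
         "use estimate_bivariate() for the unadjusted regression")
  }
  missing_cov <- setdiff(covariates, names(panel))
  if (length(missing_cov)) {
    stop("covariate column(s) absent from panel: ",
         paste(missing_cov, collapse = ", "))
  }
  df <- as.data.frame(panel)[, covariates, drop = FALSE]
  mm <- stats::model.matrix(~ ., data = df)[, -1L, drop = FALSE]
  # model.matrix drops NA rows; rebuild at full length for listwise deletion
  full <- matrix(NA_real_, nrow(df), ncol(mm), dimnames = list(NULL, colnames(mm)))
  full[as.integer(rownames(mm)), ] <- mm
  X <- cbind(ln_richness = log(panel$richness), full)
  fit_design(y = log(panel$live_mass), X = X, data = panel, factors = list(),
             cluster = panel_cluster(panel, cluster_level),
             design = "common", cluster_level = cluster_level)
}

#' Two-way fixed-effects ("Main") design
#'
#' The within estimator: absorbs a fixed effect for every plot (removing
#' all time-invariant plot and site confounders) and for every site-year
#' cell (removing site-level shocks in any year), then regresses
#' residualized ln biomass on the residualized diversity variable. The
#' slope is identified from within-plot changes in richness net of the
#' site's year shocks and, in the ln-ln form, is the richness elasticity
#' of productivity. Standard errors are CR1 cluster-robust (plot level by
#' default, allowing arbitrary within-plot serial correlation and
#' heteroskedasticity across plots) with t critical values on
#' clusters - 1 degrees of freedom.
#'
#' @param panel A `bef_panel`.
#' @param diversity_var One of `"ln_richness"` (default), `"ln_simpson"`,
#'   `"richness"` (untransformed), `"richness_quadratic"`.
#' @param extra_covariates Optional character vector of additional numeric
#'   columns to include (e.g. `"evenness"` or `"shade"`); rows missing
#'   them are removed listwise.
#' @param cluster_level `"plot"` (default) or `"site"`.
#' @return A `bef_fit`.
#' @export
estimate_main_design <- function(panel, diversity_var = "ln_richness",
                                 extra_covariates = NULL,
                                 cluster_level = "plot") {
  X <- diversity_column(panel, diversity_var)
  for (v in extra_covariates) {
    if (!v %in% names(panel)) stop("extra covariate absent from panel: ", v)
    X <- cbind(X, as.numeric(panel[[v]]))
    colnames(X)[ncol(X)] <- v
  }
  fit_design(y = log(panel$live_mass), X = X, data = panel,
             factors = fe_factors(panel, fe_spec(plot = TRUE, site_year = TRUE)),
             cluster = panel_cluster(panel, cluster_level),
             design = if (is.null(extra_covariates)) "main" else "main+covariates",
             cluster_level = cluster_level)
}

#' Moderation of the richness effect
#'
#' Adds interaction terms between ln richness and a site-level moderator
#' to the two-way fixed-effects design. The moderator's main effect is
#' absorbed by the fixed effects when it is time-invariant (site-level
#' whole-series measures); requesting it explicitly is an error rather
#' than a silently collinear column. Continuous moderators are centered
#' before interacting, so the richness coefficient remains the effect at
#' the moderator's mean; categorical moderators contribute one
#' interaction per non-reference level. A joint Wald chi-square test of
#' all interaction terms is reported.
#'
#' @param panel A `bef_panel`.
#' @param moderator Name of the moderator column.
#' @param coding `"continuous"` or `"categorical"`.
#' @param include_main_effect Must remain `FALSE`; the time-invariant main
#'   effect is not identified alongside the plot fixed effects.
#' @param cluster_level `"plot"` (default) or `"site"`.
#' @return A `bef_fit` with an extra `joint_test` element (statistic, df,
#'   p-value for all interactions = 0).
#' @export
estimate_moderation <- function(panel, moderator,
                                coding = c("continuous", "categorical"),
                                include_main_effect = FALSE,
                                cluster_level = "plot") {
  coding <- match.arg(coding)
  if (!moderator %in% names(panel)) stop("moderator column absent: ", moderator)
  if (isTRUE(include_main_effect)) {
    stop("the main effect of a time-invariant moderator is collinear with ",
         "the plot fixed effects; request interactions only")
  }
  lnR <- log(panel$richness)
  m <- panel[[moderator]]
  if (coding == "continuous") {
    mc <- as.numeric(m) - mean(as.numeric(m), na.rm = TRUE)
    X <- cbind(ln_richness = lnR, inter = lnR * mc)
    colnames(X)[2L] <- paste0("ln_richness:", moderator)
  } else {
    f <- factor(m)
    if (nlevels(f) < 2L) stop("categorical moderator needs >= 2 levels")
    dummies <- stats::model.matrix(~ f)[, -1L, drop = FALSE]
    inter <- dummies * lnR
    colnames(inter) <- paste0("ln_richness:", moderator, levels(f)[-1L])
    X <- cbind(ln_richness = lnR, inter)
  }
  fit <- fit_design(y = log(panel$live_mass), X = X, data = panel,
                    factors = fe_factors(panel, fe_spec(TRUE, TRUE)),
                    cluster = panel_cluster(panel, cluster_level),
                    design = paste0("moderation:", moderator),
                    cluster_level = cluster_level)
  idx <- grep("^ln_richness:", fit$coefficients$term)
  if (length(idx)) {
    b <- fit$coefficients$estimate[idx]
    V <- fit$vcov[idx, idx, drop = FALSE]
    stat <- drop(t(b) %*% solve(V, b))
    fit$joint_test <- list(statistic = stat, df = length(idx),
                           p_value = stats::pchisq(stat, length(idx),
                                                   lower.tail = FALSE))
  }
  fit
}
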