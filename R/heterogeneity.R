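#' Classify species into rarity-by-origin types
#'
#' Assigns each (site, species) pair to one of four types -- rare native,
#' non-rare native, non-rare non-native, rare non-native -- from a cover
#' table. Site-level abundance is either the species' mean relative cover
#' across all of the site's plot-years (absences counted as zero cover)
#' or, with `metric = "relative_frequency"`, the share of the site's
#' plot-years in which the species occurs. A species is rare at a site
#' iff its abundance is strictly below `cutoff`. Origin must be constant
#' per species within a site; plots lacking origin data are dropped with
#' a log entry.
#'
#' @param cover Cover table (`site_id`, `plot_id`, `year`, `species_id`,
#'   `relative_cover`, `origin` with values `"native"`/`"non-native"`).
#' @param cutoff Rarity threshold in (0, 1).
#' @param metric `"relative_cover"` (default) or `"relative_frequency"`.
#' @return A `species_type_table`: data frame with `site_id`,
#'   `species_id`, `abundance`, `rare`, `origin`, `type` (factor with the
#'   four levels above), plus attributes `cutoff`, `metric` and
#'   `drop_log`.
#' @export
classify_species <- function(cover, cutoff = 0.05,
                             metric = c("relative_cover", "relative_frequency")) {
  metric <- match.arg(metric)
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)")
  cover <- as.data.frame(cover)
  needed <- c("site_id", "plot_id", "year", "species_id", "relative_cover", "origin")
  miss <- setdiff(needed, names(cover))
  if (length(miss)) stop("missing cover columns: ", paste(miss, collapse = ", "))
  no_origin <- is.na(cover$origin) | !cover$origin %in% c("native", "non-native")
  dropped <- sum(no_origin)
  cover <- cover[!no_origin, , drop = FALSE]
  if (!nrow(cover)) stop("no rows with origin labels")

  out <- do.call(rbind, lapply(split(cover, cover$site_id), function(d) {
    n_py <- length(unique(paste(d$plot_id, d$year)))
    key <- d$species_id
    orig <- tapply(d$origin, key, function(o) {
      u <- unique(o)
      if (length(u) > 1L) stop("origin not constant for a species within a site")
      u
    })
    ab <- if (metric == "relative_cover") {
      tapply(d$relative_cover, key, sum) / n_py
    } else {
      tapply(paste(d$plot_id, d$year), key, function(k) length(unique(k))) / n_py
    }
    sp <- names(ab)
    data.frame(site_id = d$site_id[1L], species_id = sp,
               abundance = as.numeric(ab),
               rare = as.numeric(ab) < cutoff,
               origin = as.character(orig[sp]),
               stringsAsFactors = FALSE)
  }))
  out$type <- factor(paste0(ifelse(out$rare, "rare_", "nonrare_"),
                            ifelse(out$origin == "native", "native", "nonnative")),
                     levels = c("rare_native", "nonrare_native",
                                "nonrare_nonnative", "rare_nonnative"))
  rownames(out) <- NULL
  structure(out, cutoff = cutoff, metric = metric,
            drop_log = data.frame(reason = "missing origin", rows = dropped),
            class = c("species_type_table", "data.frame"))
}

#' Per-type richness counts
#'
#' Counts, for every plot-year in the cover table, the number of present
#' species of each rarity-by-origin type. The four counts partition total
#' richness: their sum equals the plot-year's species count.
#'
#' @param cover Cover table as in [classify_species()].
#' @param types A `species_type_table` for the same sites.
#' @return Data frame with `site_id`, `plot_id`, `year`, the four columns
#'   `R_rare_native`, `R_nonrare_native`, `R_nonrare_nonnative`,
#'   `R_rare_nonnative`, and `richness` (their sum).
#' @export
per_type_richness <- function(cover, types) {
  cover <- as.data.frame(cover)
  key_t <- paste(types$site_id, types$species_id)
  type_of <- setNames(as.character(types$type), key_t)
  cover$type <- type_of[paste(cover$site_id, cover$species_id)]
  if (anyNA(cover$type)) {
    cover <- cover[!is.na(cover$type), , drop = FALSE]
  }
  lv <- c("rare_native", "nonrare_native", "nonrare_nonnative", "rare_nonnative")
  g <- interaction(cover$site_id, cover$plot_id, cover$year, drop = TRUE)
  out <- do.call(rbind, lapply(split(cover, g), function(d) {
    counts <- table(factor(d$type, levels = lv))
    cbind(data.frame(site_id = d$site_id[1L], plot_id = d$plot_id[1L],
                     year = d$year[1L], stringsAsFactors = FALSE),
          as.data.frame(rbind(setNames(as.integer(counts), paste0("R_", lv)))))
  }))
  out$richness <- rowSums(out[, paste0("R_", lv)])
  rownames(out) <- NULL
  out[order(out$site_id, out$plot_id, out$year), , drop = FALSE]
}

#' Per-type richness effects (heterogeneous-treatment design)
#'
#' The two-way fixed-effects design with the single ln-richness regressor
#' replaced by the inverse hyperbolic sine of the four per-type richness
#' counts (IHS rather than ln because a plot-year can hold zero species
#' of a type). Coefficients are on the IHS scale: signs and relative
#' magnitudes are comparable across types, but they are not elasticities.
#' A type whose count shows no within-variation after fixed-effect
#' absorption is flagged unidentified and excluded from the fit.
#'
#' @param panel A `bef_panel` carrying columns `R_rare_native`,
#'   `R_nonrare_native`, `R_nonrare_nonnative`, `R_rare_nonnative`
#'   (e.g. merged from [per_type_richness()] or simulated with
#'   `simulate_panel(..., by_type = TRUE)`).
#' @param cluster_level `"plot"` (default) or `"site"`.
#' @return A `bef_fit` (design `"by_type"`); `unidentified` lists any
#'   excluded types.
#' @export
estimate_by_type <- function(panel, cluster_level = "plot") {
  lv <- c("rare_native", "nonrare_native", "nonrare_nonnative", "rare_nonnative")
  cols <- paste0("R_", lv)
  miss <- setdiff(cols, names(panel))
  if (length(miss)) stop("missing per-type richness columns: ",
                         paste(miss, collapse = ", "))
  X <- ihs(as.matrix(as.data.frame(panel)[, cols]))
  colnames(X) <- paste0("ihs_", cols)
  fit <- withCallingHandlers(
    fit_design(y = log(panel$live_mass), X = X, data = panel,
               factors = fe_factors(panel, fe_spec(TRUE, TRUE)),
               cluster = panel_cluster(panel, cluster_level),
               design = "by_type", cluster_level = cluster_level),
    warning = function(w) {
      if (grepl("absorbed by the fixed effects", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  fit$unidentified <- setdiff(colnames(X), fit$coefficients$term)
  fit
}

#' Equality test across the four per-type effects
#'
#' Wald chi-square test of the null that the four per-type richness
#' coefficients are equal, using the 3-contrast pairwise-difference
#' matrix against the first type and the fit's cluster-robust covariance.
#' The statistic is invariant to which type serves as the contrast base.
#'
#' @param fit A `bef_fit` from [estimate_by_type()] with all four
#'   coefficients identified.
#' @param base Index (1-4) of the base type for the contrasts; the
#'   statistic does not depend on it.
#' @return List with `statistic`, `df` (3) and `p_value`.
#' @export
equality_test <- function(fit, base = 1L) {
  terms <- grep("^ihs_R_", fit$coefficients$term)
  if (length(terms) != 4L) {
    stop("equality test needs all four per-type coefficients (",
         length(terms), " identified)")
  }
  b <- fit$coefficients$estimate[terms]
  V <- fit$vcov[terms, terms, drop = FALSE]
  C <- matrix(0, 3L, 4L)
  others <- setdiff(1:4, base)
  for (i in seq_len(3L)) {
    C[i, base] <- 1
    C[i, others[i]] <- -1
  }
  Cb <- C %*% b
  M <- C %*% V %*% t(C)
  stat <- drop(t(Cb) %*% solve(M, Cb))
  list(statistic = stat, df = 3L,
       p_value = stats::pchisq(stat, 3L, lower.tail = FALSE))
}

#' Sweep the rarity cutoff
#'
#' Re-classifies species and re-estimates the per-type design over a grid
#' of rarity cutoffs, to show how conclusions depend on where "rare" is
#' drawn.
#'
#' @param panel A `bef_panel` (without per-type columns; they are rebuilt
#'   per cutoff).
#' @param cover Cover table matching the panel.
#' @param cutoffs Numeric vector of thresholds in (0, 1).
#' @param metric Passed to [classify_species()].
#' @return Data frame with one row per cutoff and type: cutoff, type,
#'   estimate, conf_low, conf_high.
#' @export
rarity_cutoff_sweep <- function(panel, cover, cutoffs = c(0.02, 0.05, 0.1),
                                metric = "relative_cover") {
  do.call(rbind, lapply(cutoffs, function(ct) {
    types <- classify_species(cover, cutoff = ct, metric = metric)
    rk <- per_type_richness(cover, types)
    merged <- merge(as.data.frame(panel)[, setdiff(names(panel),
                                                   grep("^R_", names(panel), value = TRUE))],
                    rk[, -match("richness", names(rk))],
                    by = c("site_id", "plot_id", "year"))
    fit <- estimate_by_type(build_panel(merged,
                                        attr(panel, "inclusion_min_years")))
    cf <- fit$coefficients
    data.frame(cutoff = ct, term = cf$term, estimate = cf$estimate,
               conf_low = cf$conf_low, conf_high = cf$conf_high,
               stringsAsFactors = FALSE)
  }))
}
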