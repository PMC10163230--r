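#' Diversity metrics from a species cover table
#'
#' Computes, per plot-year: species richness (count of species with
#' positive cover), inverse Simpson diversity `1 / sum(p_i^2)` on shares
#' renormalized to sum to one, and Pielou evenness
#' `J = -sum(p_i log p_i) / log(richness)`. Evenness is undefined for a
#' single species and returned as `NA` there (not zero); the
#' evenness-controlled model variant drops those rows by listwise deletion.
#'
#' @param cover Data frame with columns `site_id`, `plot_id`, `year`,
#'   `species_id`, `relative_cover` (and optionally `origin`), one row per
#'   species present in a plot-year.
#' @return Data frame with one row per plot-year: `site_id`, `plot_id`,
#'   `year`, `richness`, `simpson_d` (inverse form), `evenness`.
#' @export
diversity_metrics <- function(cover) {
  cover <- as.data.frame(cover)
  needed <- c("site_id", "plot_id", "year", "species_id", "relative_cover")
  missing_cols <- setdiff(needed, names(cover))
  if (length(missing_cols)) {
    stop("missing cover columns: ", paste(missing_cols, collapse = ", "))
  }
  cover <- cover[cover$relative_cover > 0, , drop = FALSE]
  if (nrow(cover) == 0L) stop("no positive cover records")
  key <- interaction(cover$site_id, cover$plot_id, cover$year, drop = TRUE)
  out <- do.call(rbind, lapply(split(cover, key), function(d) {
    p <- d$relative_cover / sum(d$relative_cover)
    R <- length(p)
    data.frame(site_id = d$site_id[1L], plot_id = d$plot_id[1L],
               year = d$year[1L], richness = R,
               simpson_d = 1 / sum(p^2),
               evenness = if (R > 1L) -sum(p * log(p)) / log(R) else NA_real_)
  }))
  rownames(out) <- NULL
  out[order(out$site_id, out$plot_id, out$year), , drop = FALSE]
}
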