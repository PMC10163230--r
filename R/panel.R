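#' Build and validate a longitudinal plot-by-site-by-year panel
#'
#' Validates a long-format table of annual plot observations and applies
#' the inclusion rule: only plots observed in at least `inclusion_min_years`
#' distinct years are retained. Rows with non-positive biomass are excluded
#' (they cannot enter ln-based models) and logged. Duplicate (plot, year)
#' records and plots appearing under more than one site are errors, not
#' silent drops.
#'
#' @param raw Data frame with at least `site_id`, `plot_id`, `year`,
#'   `live_mass` (aboveground live biomass, g/m^2) and `richness`
#'   (integer species count >= 1). Further columns (covariates, `shade`,
#'   `instrument`, per-type richness) are carried through untouched.
#' @param inclusion_min_years Minimum number of observed years per plot.
#' @return A `bef_panel`: the validated data frame, ordered by site, plot,
#'   year, with attribute `drop_log` (data frame of reason/rows) recording
#'   every row removed and why.
#' @export
build_panel <- function(raw, inclusion_min_years = 5L) {
  raw <- as.data.frame(raw)
  needed <- c("site_id", "plot_id", "year", "live_mass", "richness")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  drop_log <- data.frame(reason = character(), rows = integer())
  log_drop <- function(reason, nrows) {
    if (nrows > 0) {
      drop_log <<- rbind(drop_log, data.frame(reason = reason, rows = nrows))
    }
  }
  if (nrow(raw) == 0L) {
    return(new_bef_panel(raw, drop_log, inclusion_min_years))
  }
  raw$site_id <- as.character(raw$site_id)
  raw$plot_id <- as.character(raw$plot_id)
  raw$year <- as.integer(raw$year)
  raw$live_mass <- as.numeric(raw$live_mass)
  raw$richness <- as.integer(raw$richness)

  # a plot id must map to exactly one site
  site_per_plot <- tapply(raw$site_id, raw$plot_id, function(s) length(unique(s)))
  if (any(site_per_plot > 1L)) {
    stop("plot(s) appear under more than one site: ",
         paste(names(site_per_plot)[site_per_plot > 1L], collapse = ", "))
  }
  key <- paste(raw$plot_id, raw$year, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (plot_id, year) records: ",
         paste(utils::head(unique(key[duplicated(key)]), 5), collapse = "; "))
  }
  bad_mass <- !is.finite(raw$live_mass) | raw$live_mass <= 0
  log_drop("non-positive or missing biomass", sum(bad_mass))
  raw <- raw[!bad_mass, , drop = FALSE]
  bad_rich <- !is.finite(raw$richness) | raw$richness < 1L
  log_drop("missing or invalid richness", sum(bad_rich))
  raw <- raw[!bad_rich, , drop = FALSE]

  yrs <- tapply(raw$year, raw$plot_id, function(y) length(unique(y)))
  short <- names(yrs)[yrs < inclusion_min_years]
  log_drop(sprintf("plot observed < %d years", inclusion_min_years),
           sum(raw$plot_id %in% short))
  raw <- raw[!(raw$plot_id %in% short), , drop = FALSE]

  raw <- raw[order(raw$site_id, raw$plot_id, raw$year), , drop = FALSE]
  rownames(raw) <- NULL
  new_bef_panel(raw, drop_log, inclusion_min_years)
}

new_bef_panel <- function(df, drop_log, inclusion_min_years) {
  structure(df, drop_log = drop_log,
            inclusion_min_years = inclusion_min_years,
            class = c("bef_panel", "data.frame"))
}

#' @export
print.bef_panel <- function(x, ...) {
  cat(sprintf("<bef_panel> %d plot-year rows, %d plots, %d sites\n",
              nrow(x), length(unique(x$plot_id)), length(unique(x$site_id))))
  dl <- attr(x, "drop_log")
  if (!is.null(dl) && nrow(dl)) {
    cat("dropped:", paste(sprintf("%s (%d)", dl$reason, dl$rows), collapse = "; "), "\n")
  }
  NextMethod()
  invisible(x)
}

#' Drop log of a panel
#'
#' @param panel A `bef_panel`.
#' @return Data frame with columns `reason` and `rows`.
#' @export
drop_log <- function(panel) {
  dl <- attr(panel, "drop_log")
  if (is.null(dl)) data.frame(reason = character(), rows = integer()) else dl
}

#' Read / write a panel as CSV
#'
#' Thin wrappers around [utils::read.csv()] / [utils::write.csv()] with an
#' explicit column mapping, so externally named columns can be renamed to
#' the package's canonical names before validation.
#'
#' @param path File path.
#' @param column_map Named character vector mapping canonical names
#'   (`site_id`, `plot_id`, ...) to the file's column names; identity by
#'   default.
#' @param ... Passed to [build_panel()].
#' @return A `bef_panel`.
#' @export
read_panel_csv <- function(path, column_map = NULL, ...) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw)) stop("mapped column not in file: ", src)
      names(raw)[names(raw) == src] <- canon
    }
  }
  build_panel(raw, ...)
}

#' @rdname read_panel_csv
#' @param panel A `bef_panel` to write.
#' @export
write_panel_csv <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}
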