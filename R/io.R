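#' Write simulation ground truth as JSON
#'
#' Serializes the truth record returned by [simulate_panel()] (config and
#' realized confounder draws, instrument values and latent log richness
#' and biomass) so a simulated dataset can be archived next to the CSV
#' panel and regenerated or audited later.
#'
#' @param truth The `truth` element of a [simulate_panel()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  out <- truth
  out$config <- unclass(out$config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Write a cover table as CSV
#'
#' @param cover Cover table data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cover_csv <- function(cover, path) {
  utils::write.csv(as.data.frame(cover), path, row.names = FALSE)
  invisible(path)
}
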