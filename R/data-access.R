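#' Published per-connection modulation categories
#'
#' The per-connection modulation outcomes (increase / decrease / no change
#' of EPSC amplitude under group-I mGluR activation) transcribed for the
#' three reported cohorts: human pyramidal-cell to FS-interneuron pairs
#' (n = 11), human PC to non-FS pairs (n = 13) and rat PC to FS pairs
#' (n = 14). Used to reproduce the reported category percentages with
#' [cohort_statistics()].
#'
#' @return A tibble: `connection_id`, `species`, `cell_class`, `category`.
#' @examples
#' tab <- published_connection_categories()
#' dplyr::count(tab, species, cell_class, category)
#' @export
published_connection_categories <- function() {
  f <- system.file("extdata", "connection_categories.csv",
                   package = "pairephys", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(f, stringsAsFactors = FALSE))
}
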