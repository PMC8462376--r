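#' Read a spatial OTU table from a TSV pair
#'
#' The abundance file is a tab-separated samples x OTUs matrix whose header
#' row holds OTU IDs and whose first column holds sample IDs. The metadata
#' file is tab-separated with columns `sample_id`, `transect`, `habitat`,
#' `location_index`, `x`, `y`. Samples must appear in both files.
#'
#' @param abundance_path,metadata_path Paths to the two TSV files.
#' @param habitats Allowed habitat labels.
#' @param normalized Whether the abundance values are normalized reals.
#' @return A validated [spatial_otu_table()].
#' @export
read_spatial_otu_table <- function(abundance_path, metadata_path,
                                   habitats = c("soil", "phylloplane"),
                                   normalized = FALSE) {
  ab <- readr::read_tsv(abundance_path, col_types = readr::cols(
    .default = readr::col_double(),
    sample_id = readr::col_character()
  ), progress = FALSE)
  if (!"sample_id" %in% names(ab)) {
    abort("Abundance file must have a 'sample_id' first column.")
  }
  mat <- as.matrix(ab[setdiff(names(ab), "sample_id")])
  rownames(mat) <- ab$sample_id
  md <- readr::read_tsv(metadata_path, col_types = readr::cols(
    sample_id = readr::col_character(),
    transect = readr::col_character(),
    habitat = readr::col_character(),
    location_index = readr::col_integer(),
    x = readr::col_double(),
    y = readr::col_double()
  ), progress = FALSE)
  spatial_otu_table(mat, md, habitats = habitats, normalized = normalized)
}

#' Write a spatial OTU table as a TSV pair
#'
#' Inverse of [read_spatial_otu_table()]: round trips are exact for integer
#' counts and preserve >= 15 significant digits for normalized values and
#' coordinates.
#'
#' @param table A `spatial_otu_table`.
#' @param abundance_path,metadata_path Output paths.
#' @return The input table, invisibly.
#' @export
write_spatial_otu_table <- function(table, abundance_path, metadata_path) {
  stopifnot(inherits(table, "spatial_otu_table"))
  ab <- tibble::as_tibble(table$abundance, .name_repair = "minimal")
  ab <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(table$abundance)), ab)
  readr::write_tsv(ab, abundance_path, progress = FALSE)
  readr::write_tsv(
    table$samples[, c("sample_id", "transect", "habitat", "location_index", "x", "y")],
    metadata_path, progress = FALSE
  )
  invisible(table)
}

#' Write a ground-truth table alongside a simulated study
#'
#' @param truth Ground-truth tibble from [simulate_study()].
#' @param path Output TSV path.
#' @return `truth`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  readr::write_tsv(truth, path, progress = FALSE)
  invisible(truth)
}
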