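#' Build a spatially indexed OTU table
#'
#' The universal input container: a samples x OTUs abundance matrix joined to
#' per-sample metadata placing every sample on a transect grid. Two samples
#' sharing a `(transect, location_index)` pair are the paired soil and
#' phylloplane communities collected at the same geographic point and must
#' carry identical coordinates.
#'
#' @param abundance Numeric matrix, samples in rows (rownames are sample IDs),
#'   OTUs in columns (colnames are OTU IDs). All values must be >= 0; integer
#'   read counts or normalized real values (see `normalized`).
#' @param samples Data frame with columns `sample_id`, `transect`, `habitat`,
#'   `location_index`, `x`, `y`; one row per sample, in any order.
#' @param habitats Allowed habitat labels (first label is the reference
#'   habitat in paired outputs).
#' @param normalized Logical flag: `TRUE` when `abundance` holds normalized
#'   values rather than raw read counts. Presence is abundance > 0 either way.
#'
#' @return A `spatial_otu_table` object.
#' @export
spatial_otu_table <- function(abundance, samples,
                              habitats = c("soil", "phylloplane"),
                              normalized = FALSE) {
  if (!is.matrix(abundance)) abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  samples <- tibble::as_tibble(samples)
  needed <- c("sample_id", "transect", "habitat", "location_index", "x", "y")
  missing_cols <- setdiff(needed, names(samples))
  if (length(missing_cols)) {
    abort(paste0("Sample metadata is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  samples$sample_id <- as.character(samples$sample_id)
  samples$transect <- as.character(samples$transect)
  samples$habitat <- as.character(samples$habitat)
  samples$location_index <- as.integer(samples$location_index)

  if (is.null(rownames(abundance))) {
    abort("Abundance matrix must carry sample IDs as rownames.")
  }
  if (anyDuplicated(rownames(abundance))) {
    abort(paste0("Duplicate sample ID(s) in abundance matrix: ",
                 paste(unique(rownames(abundance)[duplicated(rownames(abundance))]),
                       collapse = ", ")))
  }
  if (anyDuplicated(samples$sample_id)) {
    abort(paste0("Duplicate sample ID(s) in metadata: ",
                 paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
                       collapse = ", ")))
  }
  only_ab <- setdiff(rownames(abundance), samples$sample_id)
  only_md <- setdiff(samples$sample_id, rownames(abundance))
  if (length(only_ab) || length(only_md)) {
    abort(paste0(
      "Samples must appear in both abundance and metadata; only in abundance: [",
      paste(only_ab, collapse = ", "), "], only in metadata: [",
      paste(only_md, collapse = ", "), "]"
    ))
  }
  # align metadata order to the matrix
  samples <- samples[match(rownames(abundance), samples$sample_id), ]

  neg <- which(abundance < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    abort(sprintf("Negative abundance for sample '%s', OTU '%s'.",
                  rownames(abundance)[neg[1, 1]], colnames(abundance)[neg[1, 2]]))
  }
  if (anyNA(abundance)) abort("Abundance matrix contains missing values.")
  bad_hab <- samples$habitat[!samples$habitat %in% habitats]
  if (length(bad_hab)) {
    abort(sprintf(
      "Habitat label(s) outside {%s}: '%s' (sample '%s').",
      paste(habitats, collapse = ", "), bad_hab[[1]],
      samples$sample_id[!samples$habitat %in% habitats][[1]]
    ))
  }
  key <- paste(samples$transect, samples$location_index, samples$habitat)
  if (anyDuplicated(key)) {
    abort(sprintf(
      "Duplicate (transect, location_index, habitat) triple: %s.",
      key[duplicated(key)][[1]]
    ))
  }
  # paired samples must sit at identical coordinates
  loc_key <- paste(samples$transect, samples$location_index)
  coord_check <- stats::aggregate(
    cbind(samples$x, samples$y),
    by = list(loc = loc_key),
    FUN = function(v) length(unique(v))
  )
  bad <- coord_check$loc[coord_check$V1 > 1 | coord_check$V2 > 1]
  if (length(bad)) {
    abort(sprintf(
      "Samples at (transect location_index) '%s' disagree on coordinates; paired samples share the same point.",
      bad[[1]]
    ))
  }

  structure(
    list(
      abundance = abundance,
      samples = samples,
      habitats = habitats,
      normalized = isTRUE(normalized)
    ),
    class = "spatial_otu_table"
  )
}

#' @export
print.spatial_otu_table <- function(x, ...) {
  cat(sprintf(
    "<spatial_otu_table> %d samples x %d OTUs (%s), %d transect(s), habitats: %s\n",
    nrow(x$abundance), ncol(x$abundance),
    if (x$normalized) "normalized" else "counts",
    length(unique(x$samples$transect)),
    paste(x$habitats, collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.spatial_otu_table <- function(x) dim(x$abundance)

#' Sample identifiers, OTU identifiers
#' @param table A `spatial_otu_table`.
#' @return Character vector.
#' @export
sample_ids <- function(table) rownames(table$abundance)

#' @rdname sample_ids
#' @export
otu_ids <- function(table) colnames(table$abundance)

#' Long-format view of a spatial OTU table
#'
#' @param x A `spatial_otu_table`.
#' @param ... Unused.
#' @return A tibble with one row per (sample, OTU) cell, carrying the sample
#'   metadata alongside the abundance value.
#' @export
as_tibble.spatial_otu_table <- function(x, ...) {
  long <- tibble::tibble(
    sample_id = rep(rownames(x$abundance), times = ncol(x$abundance)),
    otu_id = rep(colnames(x$abundance), each = nrow(x$abundance)),
    abundance = as.vector(x$abundance)
  )
  dplyr::left_join(long, x$samples, by = "sample_id")
}

#' Restrict a table to a subset of samples
#'
#' @param table A `spatial_otu_table`.
#' @param sample_ids Character vector of sample IDs to keep.
#' @param drop_empty_otus Drop OTUs absent from every retained sample.
#' @return A `spatial_otu_table`.
#' @export
subset_samples <- function(table, sample_ids, drop_empty_otus = FALSE) {
  stopifnot(inherits(table, "spatial_otu_table"))
  keep <- intersect(rownames(table$abundance), sample_ids)
  ab <- table$abundance[keep, , drop = FALSE]
  if (drop_empty_otus) ab <- ab[, colSums(ab > 0) > 0, drop = FALSE]
  spatial_otu_table(ab, table$samples[table$samples$sample_id %in% keep, ],
                    habitats = table$habitats, normalized = table$normalized)
}

#' Drop study-wide singleton OTUs
#'
#' OTUs present (abundance > 0) in exactly one sample across the whole table
#' are removed; the sample set is unchanged. Community-dissimilarity analyses
#' keep singletons, while classification, occupancy and variography work on
#' the singleton-filtered table.
#'
#' @param table A `spatial_otu_table`.
#' @return A `spatial_otu_table` without singleton OTUs. Idempotent.
#' @export
remove_singletons <- function(table) {
  stopifnot(inherits(table, "spatial_otu_table"))
  prevalence <- colSums(table$abundance > 0)
  keep <- prevalence != 1L
  out <- table
  out$abundance <- table$abundance[, keep, drop = FALSE]
  out
}

#' Normalize counts for variography
#'
#' Applies log(1 + count) cell-wise and flags the table normalized; applied to
#' an already-normalized table it returns the input unchanged. Downstream
#' range estimation expects a variance-stabilized abundance scale; users with
#' their own normalization (e.g. a VST table) can supply it directly via
#' `normalized = TRUE` in [spatial_otu_table()].
#'
#' @param table A `spatial_otu_table`.
#' @return A normalized `spatial_otu_table`.
#' @export
normalize_log1p <- function(table) {
  stopifnot(inherits(table, "spatial_otu_table"))
  if (table$normalized) return(table)
  out <- table
  out$abundance <- log1p(table$abundance)
  out$normalized <- TRUE
  out
}

# Internal: tibble of complete soil/phylloplane pairs.
# One row per (transect, location_index) with both habitats present,
# carrying the two sample ids; warns about unpaired locations.
complete_pairs <- function(table, quiet = FALSE) {
  h1 <- table$habitats[[1]]
  h2 <- table$habitats[[2]]
  md <- table$samples
  wide <- tidyr::pivot_wider(
    md[, c("transect", "location_index", "habitat", "sample_id")],
    names_from = "habitat", values_from = "sample_id"
  )
  if (!h1 %in% names(wide)) wide[[h1]] <- NA_character_
  if (!h2 %in% names(wide)) wide[[h2]] <- NA_character_
  incomplete <- is.na(wide[[h1]]) | is.na(wide[[h2]])
  if (any(incomplete) && !quiet) {
    warn(sprintf("%d location(s) lack a complete habitat pair and were skipped.",
                 sum(incomplete)))
  }
  out <- wide[!incomplete, ]
  out <- out[order(out$transect, out$location_index), ]
  tibble::tibble(
    transect = out$transect,
    location_index = out$location_index,
    sample_1 = out[[h1]],
    sample_2 = out[[h2]]
  )
}
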