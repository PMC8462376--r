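#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain with the protocol's stated
#' values as defaults. Exactly one of `synthetic` (a [synthetic_params()])
#' or the `abundance_path`/`metadata_path` pair must be supplied to
#' [run_pipeline()].
#'
#' @param seed Master seed; each stage derives its own stream from it.
#' @param abundance_path,metadata_path Input TSVs (see
#'   [read_spatial_otu_table()]); `NULL` when simulating.
#' @param synthetic A [synthetic_params()] or `NULL`.
#' @param output_dir Directory for stage outputs and the run manifest.
#' @param n_permutations Permutations for Mantel/permanova (default 999).
#' @param n_randomizations Derangements in the paired-habitat null.
#' @param alpha Significance level used throughout.
#' @param min_range_m Variogram culling threshold (meters).
#' @param outlier_rule Passed to [cull_and_flag()].
#' @param variogram_bins,variogram_min_pairs Binning controls.
#' @param loess_span,loess_degree Occupancy-abundance smoother controls.
#' @param kriging_resolution Map grid spacing (meters).
#' @param max_maps Cap on paired maps rendered per run.
#' @param mantel_min_present Minimum occupancy for a Mantel screen candidate.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            abundance_path = NULL, metadata_path = NULL,
                            synthetic = NULL,
                            output_dir = tempfile("mycospat_run_"),
                            n_permutations = 999L,
                            n_randomizations = 99L,
                            alpha = 0.05,
                            min_range_m = 1,
                            outlier_rule = "diagonal",
                            variogram_bins = 12L,
                            variogram_min_pairs = 10L,
                            loess_span = 0.75,
                            loess_degree = 2L,
                            kriging_resolution = 0.5,
                            max_maps = 4L,
                            mantel_min_present = 5L) {
  structure(
    list(
      seed = as.integer(seed),
      abundance_path = abundance_path, metadata_path = metadata_path,
      synthetic = synthetic, output_dir = output_dir,
      n_permutations = as.integer(n_permutations),
      n_randomizations = as.integer(n_randomizations),
      alpha = alpha, min_range_m = min_range_m, outlier_rule = outlier_rule,
      variogram_bins = as.integer(variogram_bins),
      variogram_min_pairs = as.integer(variogram_min_pairs),
      loess_span = loess_span, loess_degree = as.integer(loess_degree),
      kriging_resolution = kriging_resolution,
      max_maps = max_maps,
      mantel_min_present = as.integer(mantel_min_present)
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; an optional
#' `synthetic` mapping mirrors [synthetic_params()] (with a nested `design`
#' mapping mirroring [study_design()]). A seed is mandatory.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) abort("Config must set an explicit seed.")
  syn <- NULL
  if (!is.null(raw$synthetic)) {
    syn_args <- raw$synthetic
    if (!is.null(syn_args$design)) {
      syn_args$design <- do.call(study_design, syn_args$design)
    }
    if (is.null(syn_args$seed)) syn_args$seed <- raw$seed
    syn <- do.call(synthetic_params, syn_args)
  }
  raw$synthetic <- NULL
  do.call(pipeline_config, c(raw, list(synthetic = syn)))
}

write_stage_tsv <- function(x, dir, name) {
  path <- file.path(dir, paste0(name, ".tsv"))
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  path
}

#' Run the full spatial analysis pipeline
#'
#' Simulate (or ingest) the paired-habitat OTU table, then run every stage in
#' order: inter-habitat spatial autocorrelation test, singleton removal,
#' specialist/generalist classification, occupancy comparison, Mantel
#' screen, range estimation with culling, class-wise range comparison,
#' paired kriged maps, and occupancy-abundance curves. All stage outputs are
#' written as TSV under `config$output_dir`, followed by a JSON run
#' manifest; outputs are deterministic given the config and seed.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest (list), invisibly. Also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 6L)
  timings <- list()
  outputs <- character()
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    message(sprintf("[mycospat] stage %-18s ...", name), appendLF = FALSE)
    res <- force(code)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    message(sprintf(" %.2fs", timings[[name]]))
    res
  }

  table <- stage("input", {
    if (!is.null(config$synthetic)) {
      sim <- simulate_study(config$synthetic)
      outputs <- c(outputs, write_stage_tsv(sim$truth, config$output_dir,
                                             "ground_truth"))
      write_spatial_otu_table(sim$table,
                              file.path(config$output_dir, "abundance.tsv"),
                              file.path(config$output_dir, "metadata.tsv"))
      outputs <- c(outputs, file.path(config$output_dir, "abundance.tsv"),
                    file.path(config$output_dir, "metadata.tsv"))
      sim$table
    } else if (!is.null(config$abundance_path) &&
               !is.null(config$metadata_path)) {
      read_spatial_otu_table(config$abundance_path, config$metadata_path)
    } else {
      abort("Config names neither input TSVs nor synthetic parameters.")
    }
  })

  paired <- stage("paired_habitat", {
    res <- inter_habitat_test(table, scale = "both",
                              n_randomizations = config$n_randomizations,
                              seed = seeds[[1]], alpha = config$alpha)
    outputs <- c(outputs, write_stage_tsv(res, config$output_dir,
                                           "paired_habitat"))
    res
  })

  filtered <- remove_singletons(table)

  classifications <- stage("classification", {
    cl <- classify_otus(filtered, scope = "transect")
    outputs <- c(outputs, write_stage_tsv(cl, config$output_dir,
                                           "classifications"))
    cl
  })

  occ_cmp <- stage("occupancy", {
    cmp <- compare_occupancy(classifications)
    outputs <- c(outputs,
                  write_stage_tsv(cmp$comparisons, config$output_dir,
                                  "occupancy_comparisons"),
                  write_stage_tsv(cmp$summary, config$output_dir,
                                  "occupancy_summary"))
    cmp
  })

  ranged <- stage("variography", {
    classified <- classifications[classifications$label != "unclassified", ]
    cand <- dplyr::bind_rows(
      tibble::tibble(otu_id = classified$otu_id,
                     transect = classified$transect,
                     habitat = "soil")[classified$label != "phylloplane_specialist", ],
      tibble::tibble(otu_id = classified$otu_id,
                     transect = classified$transect,
                     habitat = "phylloplane")[classified$label != "soil_specialist", ]
    )
    screen <- mantel_screen(filtered, candidates = cand,
                            alpha = config$alpha,
                            n_permutations = config$n_permutations,
                            seed = seeds[[2]],
                            min_present = config$mantel_min_present)
    outputs <- c(outputs, write_stage_tsv(screen, config$output_dir,
                                           "mantel_screen"))
    est <- estimate_ranges(filtered, screen, classifications,
                           n_bins = config$variogram_bins,
                           min_pairs = config$variogram_min_pairs)
    cull <- cull_and_flag(est, min_range_m = config$min_range_m,
                          outlier_rule = config$outlier_rule)
    outputs <- c(outputs,
                  write_stage_tsv(cull$estimates, config$output_dir,
                                  "range_estimates"),
                  write_stage_tsv(cull$audit, config$output_dir,
                                  "cull_audit"))
    cmp <- compare_ranges(cull)
    outputs <- c(outputs,
                  write_stage_tsv(cmp$comparisons, config$output_dir,
                                  "range_comparisons"),
                  write_stage_tsv(cmp$summary, config$output_dir,
                                  "range_summary"))
    cull
  })

  maps <- stage("kriging", {
    mp <- paired_surface_maps(filtered, ranged,
                              grid_resolution = config$kriging_resolution,
                              max_pairs = config$max_maps)
    outputs <- c(outputs, write_stage_tsv(mp$summary, config$output_dir,
                                           "map_synchrony"))
    for (nm in names(mp$surfaces)) {
      for (hab in names(mp$surfaces[[nm]])) {
        outputs <- c(outputs, write_stage_tsv(
          mp$surfaces[[nm]][[hab]], config$output_dir,
          paste0("surface_", gsub("[^A-Za-z0-9]+", "_", nm), "_", hab)
        ))
      }
    }
    mp
  })

  oa <- stage("occupancy_abundance", {
    pts <- occupancy_abundance_points(normalize_log1p(filtered),
                                      classifications)
    outputs <- c(outputs, write_stage_tsv(pts, config$output_dir,
                                           "oa_points"))
    curves <- purrr::map_dfr(split(pts, pts$habitat), function(sub) {
      sub <- sub[sub$local_abundance > 0, ]
      if (nrow(sub) < max(5, config$loess_degree + 2) ||
          length(unique(sub$occupancy)) < 3) {
        return(NULL)
      }
      cv <- loess_curve(sub$occupancy, log10(sub$local_abundance),
                        span = config$loess_span,
                        degree = config$loess_degree)
      cv$habitat <- sub$habitat[[1]]
      cv
    })
    outputs <- c(outputs, write_stage_tsv(curves, config$output_dir,
                                           "oa_curves"))
    list(points = pts, curves = curves)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("mycospat")),
    seed = config$seed,
    config = {
      snap <- unclass(config)
      snap[!vapply(snap, is.null, logical(1)) & names(snap) != "synthetic"]
    },
    synthetic = !is.null(config$synthetic),
    n_samples = nrow(table$abundance),
    n_otus = ncol(table$abundance),
    audit = as.list(ranged$audit),
    n_maps = nrow(maps$summary),
    stage_timings_s = timings,
    outputs = basename(outputs)
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
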