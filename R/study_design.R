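#' Describe a grid-transect, paired-habitat sampling design
#'
#' A design is a set of identical rectangular grid transects, each sampled at
#' `grid_rows * grid_cols` locations, with every location sampled once per
#' habitat. The default reproduces the two-island survey layout of six
#' 10 m x 40 m forest transects with 36 paired soil/phylloplane samples each,
#' 432 community samples in total.
#'
#' The survey protocol fixes only the number of locations per transect (36),
#' not their exact grid geometry; the 3-column by 12-row default spans the
#' 10 m x 40 m transect with 5 m column spacing and 40/11 m row spacing and
#' can be overridden.
#'
#' @param n_transects Number of transects.
#' @param grid_rows,grid_cols Grid dimensions within a transect.
#' @param spacing_x,spacing_y Distance in meters between neighbouring grid
#'   columns / rows.
#' @param habitats Character vector of habitat labels sampled at every
#'   location; exactly two in the paired design.
#'
#' @return A `study_design` object (list) with the fields above plus derived
#'   counts `locations_per_transect` and `n_samples`.
#' @examples
#' d <- study_design()
#' d$n_samples # 432
#' @export
study_design <- function(n_transects = 6L,
                         grid_rows = 12L,
                         grid_cols = 3L,
                         spacing_x = 5,
                         spacing_y = 40 / 11,
                         habitats = c("soil", "phylloplane")) {
  n_transects <- as.integer(n_transects)
  grid_rows <- as.integer(grid_rows)
  grid_cols <- as.integer(grid_cols)
  if (n_transects < 1L || grid_rows < 1L || grid_cols < 1L) {
    abort("n_transects, grid_rows and grid_cols must be positive integers.")
  }
  if (spacing_x <= 0 || spacing_y <= 0) {
    abort("Grid spacings must be strictly positive (meters).")
  }
  habitats <- as.character(habitats)
  if (length(habitats) != 2L || anyDuplicated(habitats)) {
    abort("The paired design requires exactly 2 distinct habitat labels.")
  }
  structure(
    list(
      n_transects = n_transects,
      grid_rows = grid_rows,
      grid_cols = grid_cols,
      spacing_x = spacing_x,
      spacing_y = spacing_y,
      habitats = habitats,
      locations_per_transect = grid_rows * grid_cols,
      n_samples = grid_rows * grid_cols * length(habitats) * n_transects
    ),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "<study_design> %d transect(s), %d x %d grid (%g m x %g m spacing), habitats: %s\n",
    x$n_transects, x$grid_cols, x$grid_rows, x$spacing_x, x$spacing_y,
    paste(x$habitats, collapse = ", ")
  ))
  cat(sprintf(
    "  %d locations/transect, %d community samples in total\n",
    x$locations_per_transect, x$n_samples
  ))
  invisible(x)
}

#' Grid coordinates of one transect
#'
#' Local within-transect coordinates in meters, origin at the transect corner.
#' Locations are numbered column-major: location_index runs down each column of
#' the grid.
#'
#' @param design A [study_design()].
#' @return A tibble with columns `location_index`, `x`, `y`.
#' @export
design_coords <- function(design) {
  stopifnot(inherits(design, "study_design"))
  grid <- expand.grid(
    row = seq_len(design$grid_rows) - 1L,
    col = seq_len(design$grid_cols) - 1L
  )
  tibble::tibble(
    location_index = seq_len(nrow(grid)),
    x = grid$col * design$spacing_x,
    y = grid$row * design$spacing_y
  )
}
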