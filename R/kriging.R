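#' Ordinary kriging of one variable over a regular grid
#'
#' Solves the ordinary-kriging system at every node of a regular grid
#' covering the data bounding box, using the fitted zero-nugget exponential
#' variogram: weights satisfy the unbiasedness constraint (sum to 1) via a
#' Lagrange multiplier, predictions are the weighted data values, and the
#' kriging variance is `sum(w_i * gamma(h_i0)) + mu`. With a zero nugget the
#' predictor interpolates exactly: at a data location the prediction equals
#' the observation and the standard error vanishes. Duplicate coordinates
#' are averaged first (they would make the system singular).
#'
#' All data points enter every system (global neighborhood) — transects hold
#' at most a few dozen points.
#'
#' @param values Numeric vector of observations.
#' @param coords Data frame with columns `x`, `y` in meters.
#' @param model A `variogram_model` from [fit_exponential()].
#' @param grid_resolution Node spacing in meters (default 0.5).
#' @param grid Optional tibble of prediction points (`x`, `y`) overriding the
#'   regular grid.
#' @return A `kriged_surface` tibble (`x`, `y`, `prediction`,
#'   `standard_error`) with attributes `model` and `weight_sums` (kriging
#'   weight totals per node, all 1 up to solver tolerance).
#' @export
ordinary_kriging <- function(values, coords, model, grid_resolution = 0.5,
                             grid = NULL) {
  stopifnot(inherits(model, "variogram_model"), length(values) >= 2)
  coords <- as.data.frame(coords)[, c("x", "y")]
  stopifnot(nrow(coords) == length(values))
  if (!model$converged) {
    warn("Variogram model is flagged non-converged; kriging with it anyway.")
  }

  key <- paste(coords$x, coords$y)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    inform(sprintf("ordinary_kriging: averaging %d duplicated coordinate(s): %s",
                   length(dup), paste(head(dup, 3), collapse = "; ")))
    means <- tapply(values, key, mean)
    first <- !duplicated(key)
    coords <- coords[first, , drop = FALSE]
    values <- as.numeric(means[key[first]])
  }

  n <- nrow(coords)
  h <- as.matrix(dist(coords))
  gamma_dd <- variogram_gamma(model, h)
  A <- rbind(cbind(gamma_dd, 1), c(rep(1, n), 0))

  if (is.null(grid)) {
    gx <- seq(min(coords$x), max(coords$x), by = grid_resolution)
    gy <- seq(min(coords$y), max(coords$y), by = grid_resolution)
    grid <- expand.grid(x = gx, y = gy)
  }
  grid <- as.data.frame(grid)
  m <- nrow(grid)
  # gamma between each datum and each prediction node
  dx <- outer(coords$x, grid$x, "-")
  dy <- outer(coords$y, grid$y, "-")
  gamma_d0 <- variogram_gamma(model, sqrt(dx^2 + dy^2))
  B <- rbind(gamma_d0, rep(1, m))
  sol <- tryCatch(solve(A, B), error = function(e) {
    abort(paste0("Singular kriging system (co-located points with zero nugget?): ",
                 conditionMessage(e)))
  })
  w <- sol[seq_len(n), , drop = FALSE]
  mu <- sol[n + 1, ]
  pred <- drop(crossprod(w, values))
  kvar <- colSums(w * gamma_d0) + mu
  out <- tibble::tibble(
    x = grid$x, y = grid$y,
    prediction = pred,
    standard_error = sqrt(pmax(kvar, 0))
  )
  attr(out, "model") <- model
  attr(out, "weight_sums") <- colSums(w)
  class(out) <- c("kriged_surface", class(out))
  out
}

#' Plot a kriged surface
#'
#' Abundance surfaces use a perceptually uniform dark-to-light fill: dark is
#' low abundance, light is high.
#'
#' @param object A `kriged_surface`.
#' @param what `"prediction"` or `"standard_error"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kriged_surface <- function(object, what = c("prediction", "standard_error"),
                                    ...) {
  what <- match.arg(what)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       fill = .data[[what]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = what) +
    ggplot2::theme_minimal()
}

#' Paired soil/phylloplane kriged maps for qualifying generalists
#'
#' Selects OTUs that are generalists in a transect, passed the Mantel screen
#' in both habitats there, and survived culling in both habitats; kriges the
#' OTU's normalized abundance in each habitat on a common grid and reports
#' the cross-habitat synchrony (Pearson correlation of the two prediction
#' rasters).
#'
#' @param table A `spatial_otu_table` (normalized, or counts to be log1p
#'   transformed).
#' @param cull A [cull_and_flag()] result whose estimates carry labels.
#' @param grid_resolution Meters between grid nodes (default 0.5).
#' @param max_pairs Optional cap on the number of OTU-transect pairs mapped.
#' @return A `paired_surfaces` list with `summary` (tibble: `otu_id`,
#'   `transect`, `synchrony`) and `surfaces` (named list of
#'   `list(soil = , phylloplane = )` kriged surfaces). Empty when no OTU
#'   qualifies.
#' @export
paired_surface_maps <- function(table, cull, grid_resolution = 0.5,
                                max_pairs = Inf) {
  stopifnot(inherits(table, "spatial_otu_table"))
  est <- if (inherits(cull, "cull_result")) cull$estimates else cull
  norm <- normalize_log1p(table)
  ok <- est[!est$culled & !est$outlier &
              !is.na(est$label) & est$label == "generalist", ]
  both <- dplyr::filter(
    dplyr::count(ok, .data$otu_id, .data$transect),
    .data$n == 2
  )
  if (nrow(both) > max_pairs) both <- both[seq_len(max_pairs), ]
  md <- norm$samples
  surfaces <- list()
  summary <- purrr::map_dfr(seq_len(nrow(both)), function(k) {
    otu <- both$otu_id[[k]]
    tr <- both$transect[[k]]
    sub_est <- ok[ok$otu_id == otu & ok$transect == tr, ]
    tr_md <- md[md$transect == tr, ]
    gx <- seq(min(tr_md$x), max(tr_md$x), by = grid_resolution)
    gy <- seq(min(tr_md$y), max(tr_md$y), by = grid_resolution)
    grid <- expand.grid(x = gx, y = gy)
    pair <- purrr::map(seq_len(nrow(sub_est)), function(j) {
      hab <- sub_est$habitat[[j]]
      ids <- tr_md$sample_id[tr_md$habitat == hab]
      model <- structure(
        list(model_type = "exponential", nugget = 0,
             sill = sub_est$sill[[j]], range_param = sub_est$range_param[[j]],
             effective_range = sub_est$effective_range[[j]],
             sse = sub_est$sse[[j]], converged = sub_est$converged[[j]]),
        class = "variogram_model"
      )
      surf <- ordinary_kriging(
        norm$abundance[ids, otu],
        md[match(ids, md$sample_id), c("x", "y")],
        model, grid = grid
      )
      attr(surf, "otu_id") <- otu
      attr(surf, "habitat") <- hab
      attr(surf, "transect") <- tr
      surf
    })
    names(pair) <- sub_est$habitat
    surfaces[[paste(otu, tr, sep = "@")]] <<- pair
    tibble::tibble(
      otu_id = otu, transect = tr,
      synchrony = cor(pair[[1]]$prediction, pair[[2]]$prediction)
    )
  })
  if (nrow(both) == 0) {
    inform("paired_surface_maps: no qualifying generalist OTUs.")
    summary <- tibble::tibble(otu_id = character(), transect = character(),
                              synchrony = numeric())
  }
  structure(list(summary = summary, surfaces = surfaces),
            class = "paired_surfaces")
}

#' @export
print.paired_surfaces <- function(x, ...) {
  cat(sprintf("<paired_surfaces> %d paired map(s)\n", nrow(x$summary)))
  if (nrow(x$summary)) print(x$summary)
  invisible(x)
}

#' Plot a coupled soil/phylloplane map pair
#'
#' @param object A `paired_surfaces` result.
#' @param which Index or name of the pair to draw.
#' @param ... Unused.
#' @return A ggplot with one facet per habitat.
#' @export
autoplot.paired_surfaces <- function(object, which = 1, ...) {
  pair <- object$surfaces[[which]]
  dat <- dplyr::bind_rows(purrr::imap(pair, function(surf, hab) {
    tibble::tibble(x = surf$x, y = surf$y, prediction = surf$prediction,
                   habitat = hab)
  }))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y,
                                    fill = .data$prediction)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~habitat) +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = "abundance") +
    ggplot2::theme_minimal()
}
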