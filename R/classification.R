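#' Per-OTU occupancy within transects
#'
#' Occupancy is the number of samples within one transect and habitat in
#' which an OTU occurs (abundance > 0). Run on the singleton-filtered table
#' for classification work; the cap is the number of sampling locations per
#' transect (36 in the default design).
#'
#' @param table A `spatial_otu_table`.
#' @return A tibble with columns `otu_id`, `transect`, `habitat`,
#'   `occupancy`, including zero rows for OTUs absent from a
#'   transect-habitat.
#' @export
otu_occupancy <- function(table) {
  stopifnot(inherits(table, "spatial_otu_table"))
  pres <- (table$abundance > 0) * 1
  grp <- paste(table$samples$transect, table$samples$habitat, sep = "\r")
  agg <- rowsum(pres, grp) # groups x OTUs occurrence counts
  keys <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
  out <- tibble::tibble(
    transect = rep(keys[, 1], times = ncol(agg)),
    habitat = rep(keys[, 2], times = ncol(agg)),
    otu_id = rep(colnames(agg), each = nrow(agg)),
    occupancy = as.integer(agg)
  )
  # complete missing transect x habitat combinations with zeros
  out <- tidyr::complete(
    out,
    transect = unique(table$samples$transect),
    habitat = table$habitats,
    otu_id = otu_ids(table),
    fill = list(occupancy = 0L)
  )
  dplyr::arrange(out[, c("otu_id", "transect", "habitat", "occupancy")],
                 .data$otu_id, .data$transect, .data$habitat)
}

#' Classify OTUs as habitat specialists or generalists
#'
#' Occurrence-based rules applied within each transect (or study-wide):
#' an OTU is a *generalist* when it occurs more than once in each habitat,
#' a *specialist* when it occurs more than once and exclusively in a single
#' habitat, and *unclassified* otherwise (e.g. 2 soil + 1 phylloplane
#' occurrences fails both rules). Apply to the singleton-filtered table.
#'
#' @param table A `spatial_otu_table` (singletons removed).
#' @param scope `"transect"` (the rule as defined; one label per OTU per
#'   transect) or `"study"` (occupancies pooled study-wide before applying
#'   the same rules; used for study-wide richness tallies).
#' @return An `otu_classification` tibble: `otu_id`, `transect` (`"study"`
#'   in study scope), `occupancy_soil`, `occupancy_phyllo`, `label` in
#'   {`soil_specialist`, `phylloplane_specialist`, `generalist`,
#'   `unclassified`}.
#' @export
classify_otus <- function(table, scope = c("transect", "study")) {
  scope <- match.arg(scope)
  stopifnot(inherits(table, "spatial_otu_table"))
  occ <- otu_occupancy(table)
  h1 <- table$habitats[[1]]
  h2 <- table$habitats[[2]]
  if (scope == "study") {
    occ <- dplyr::summarise(
      dplyr::group_by(occ, .data$otu_id, .data$habitat),
      occupancy = sum(.data$occupancy), .groups = "drop"
    )
    occ$transect <- "study"
  }
  wide <- tidyr::pivot_wider(occ, names_from = "habitat",
                             values_from = "occupancy", values_fill = 0L)
  o1 <- wide[[h1]]
  o2 <- wide[[h2]]
  label <- dplyr::case_when(
    o1 >= 2 & o2 >= 2 ~ "generalist",
    o1 >= 2 & o2 == 0 ~ paste0(h1, "_specialist"),
    o2 >= 2 & o1 == 0 ~ paste0(h2, "_specialist"),
    .default = "unclassified"
  )
  out <- tibble::tibble(
    otu_id = wide$otu_id,
    transect = wide$transect,
    occupancy_soil = as.integer(o1),
    occupancy_phyllo = as.integer(o2),
    label = label
  )
  class(out) <- c("otu_classification", class(out))
  out
}

# Internal: class-habitat occupancy groups behind the occupancy comparison.
# Specialists contribute their home-habitat occupancy; generalists one entry
# per habitat.
occupancy_groups <- function(classifications) {
  cl <- classifications[classifications$label != "unclassified", ]
  dplyr::bind_rows(
    tibble::tibble(
      group = "soil_specialist:soil",
      occupancy = cl$occupancy_soil[cl$label == "soil_specialist"]
    ),
    tibble::tibble(
      group = "phylloplane_specialist:phylloplane",
      occupancy = cl$occupancy_phyllo[cl$label == "phylloplane_specialist"]
    ),
    tibble::tibble(
      group = "generalist:soil",
      occupancy = cl$occupancy_soil[cl$label == "generalist"]
    ),
    tibble::tibble(
      group = "generalist:phylloplane",
      occupancy = cl$occupancy_phyllo[cl$label == "generalist"]
    )
  )
}

#' Compare occupancy between specialist/generalist class-habitat groups
#'
#' Pairwise Wilcoxon rank-sum tests over the four class-habitat occupancy
#' groups (soil specialists, phylloplane specialists, generalists in soil,
#' generalists in phylloplane), Benjamini-Hochberg corrected across the pair
#' set, with per-group medians and interquartile ranges.
#'
#' @param classifications An [classify_otus()] result.
#' @return A list with `comparisons` (tibble: `group_a`, `group_b`,
#'   `statistic`, `p_value`, `p_adjusted`) and `summary` (tibble: `group`,
#'   `n`, `median`, `iqr`). Groups with fewer than 2 observations are
#'   skipped with a warning; with < 2 usable groups the comparison table is
#'   empty.
#' @export
compare_occupancy <- function(classifications) {
  groups <- occupancy_groups(classifications)
  compare_groups(groups, "occupancy")
}

# Internal shared engine for pairwise Wilcoxon + BH group comparisons.
compare_groups <- function(groups, value_col) {
  split_vals <- split(groups[[value_col]], groups$group)
  split_vals <- split_vals[lengths(split_vals) > 0]
  summary <- tibble::tibble(
    group = names(split_vals),
    n = lengths(split_vals),
    median = vapply(split_vals, median, numeric(1)),
    iqr = vapply(split_vals, function(v) stats::IQR(v), numeric(1))
  )
  usable <- names(split_vals)[lengths(split_vals) >= 2]
  skipped <- setdiff(names(split_vals), usable)
  if (length(skipped)) {
    warn(paste0("Group(s) with < 2 observations skipped: ",
                paste(skipped, collapse = ", ")))
  }
  if (length(usable) < 2) {
    comparisons <- tibble::tibble(
      group_a = character(), group_b = character(),
      statistic = numeric(), p_value = numeric(), p_adjusted = numeric()
    )
  } else {
    pairs <- combn(usable, 2)
    comparisons <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      w <- wilcoxon_rank_sum(split_vals[[pairs[1, k]]],
                             split_vals[[pairs[2, k]]])
      tibble::tibble(
        group_a = pairs[1, k], group_b = pairs[2, k],
        statistic = w$statistic, p_value = w$p_value
      )
    })
    comparisons$p_adjusted <- benjamini_hochberg(comparisons$p_value)
  }
  list(comparisons = comparisons, summary = summary)
}

#' Occupancy-abundance points
#'
#' One point per (OTU, transect, habitat) with occupancy >= 1: `occupancy`
#' is the within-transect occurrence count and `local_abundance` the sum of
#' the OTU's normalized abundance across its occupied samples divided by the
#' occupancy — mean abundance where present.
#'
#' @param table A normalized `spatial_otu_table` (see [normalize_log1p()]).
#' @param classifications Optional [classify_otus()] result (transect scope)
#'   used to attach class labels.
#' @return A tibble: `otu_id`, `transect`, `habitat`, `label`, `occupancy`,
#'   `local_abundance`.
#' @export
occupancy_abundance_points <- function(table, classifications = NULL) {
  stopifnot(inherits(table, "spatial_otu_table"))
  if (!table$normalized) {
    warn("Table is not normalized; local abundance computed on raw counts.")
  }
  grp <- paste(table$samples$transect, table$samples$habitat, sep = "\r")
  tot <- rowsum(table$abundance, grp)
  occ <- rowsum((table$abundance > 0) * 1, grp)
  keys <- do.call(rbind, strsplit(rownames(tot), "\r", fixed = TRUE))
  pts <- tibble::tibble(
    transect = rep(keys[, 1], times = ncol(tot)),
    habitat = rep(keys[, 2], times = ncol(tot)),
    otu_id = rep(colnames(tot), each = nrow(tot)),
    occupancy = as.integer(occ),
    local_abundance = as.vector(ifelse(occ > 0, tot / pmax(occ, 1), NA_real_))
  )
  pts <- pts[pts$occupancy >= 1, ]
  if (!is.null(classifications)) {
    pts <- dplyr::left_join(
      pts, classifications[, c("otu_id", "transect", "label")],
      by = c("otu_id", "transect")
    )
  } else {
    pts$label <- NA_character_
  }
  pts[, c("otu_id", "transect", "habitat", "label", "occupancy",
          "local_abundance")]
}

#' Local polynomial (loess-style) smoother with tricube weights
#'
#' Fits a weighted polynomial of the given degree around each point of an
#' even grid across the x range, using tricube weights over the `span`
#' fraction of nearest neighbours, and returns a pointwise confidence
#' interval from the local weighted fit.
#'
#' @param x,y Numeric vectors (>= max(5, degree + 2) points).
#' @param span Fraction of points receiving positive weight at each fit
#'   (0 < span <= 1).
#' @param degree Local polynomial degree (1 or 2).
#' @param n_grid Number of evaluation points.
#' @param level Confidence level for the interval.
#' @return A tibble: `x`, `fit`, `se`, `lower`, `upper`.
#' @export
loess_curve <- function(x, y, span = 0.75, degree = 2, n_grid = 50,
                        level = 0.95) {
  stopifnot(length(x) == length(y), span > 0, span <= 1, degree %in% 1:2)
  n <- length(x)
  if (n < max(5, degree + 2)) abort("Too few points for a local fit.")
  grid <- seq(min(x), max(x), length.out = n_grid)
  q <- max(ceiling(span * n), degree + 1)
  fits <- purrr::map_dfr(grid, function(x0) {
    d <- abs(x - x0)
    h <- sort(d)[q]
    if (h == 0) h <- max(d[d > 0][1], .Machine$double.eps)
    w <- pmax(1 - (d / h)^3, 0)^3
    pos <- sum(w > 0)
    if (pos < degree + 1) {
      abort(sprintf("Span %.3g leaves %d point(s) in the window at x = %.4g; need %d.",
                    span, pos, x0, degree + 1))
    }
    xx <- x - x0 # center so the intercept is the fitted value
    X <- stats::poly(xx, degree, raw = TRUE, simple = TRUE)
    fit <- stats::lm.wfit(cbind(1, X), y, w)
    used <- w > 0
    dfres <- max(sum(used) - (degree + 1), 1)
    sigma2 <- sum(w[used] * fit$residuals[used]^2) / dfres
    # variance of the intercept of the weighted fit
    XtWX <- crossprod(cbind(1, X) * sqrt(w))
    v <- tryCatch(solve(XtWX)[1, 1], error = function(e) NA_real_)
    se <- sqrt(sigma2 * v)
    tibble::tibble(x = x0, fit = fit$coefficients[[1]], se = se)
  })
  tcrit <- qt(1 - (1 - level) / 2, df = max(n - (degree + 1), 1))
  fits$lower <- fits$fit - tcrit * fits$se
  fits$upper <- fits$fit + tcrit * fits$se
  fits
}

#' Plot occupancy-abundance relationships with a smoothed curve
#'
#' @param points An [occupancy_abundance_points()] tibble.
#' @param span,degree Passed to [loess_curve()], fitted per habitat.
#' @return A ggplot of log10 local abundance against occupancy.
#' @export
plot_occupancy_abundance <- function(points, span = 0.75, degree = 2) {
  pts <- points[points$local_abundance > 0, ]
  pts$log_abundance <- log10(pts$local_abundance)
  curves <- dplyr::group_modify(
    dplyr::group_by(pts, .data$habitat),
    ~ loess_curve(.x$occupancy, .x$log_abundance, span = span, degree = degree)
  )
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$occupancy)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$log_abundance,
                                     colour = .data$label), alpha = 0.5) +
    ggplot2::geom_ribbon(
      data = curves,
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper, x = .data$x),
      alpha = 0.25, inherit.aes = FALSE
    ) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(x = .data$x, y = .data$fit)) +
    ggplot2::facet_wrap(~habitat) +
    ggplot2::labs(x = "occupancy (samples per transect)",
                  y = "log10 local abundance") +
    ggplot2::theme_minimal()
}
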