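#' Mantel screen for spatially autocorrelated OTUs
#'
#' For each candidate (OTU, transect, habitat), correlates the single-OTU
#' Bray-Curtis distance on per-sample relative abundance
#' (`|x_i - x_j| / (x_i + x_j)`, defined 0 when both are 0) with geographic
#' distance, and flags candidates whose one-sided Mantel p-value is at most
#' `alpha`.
#'
#' @param table A `spatial_otu_table` of raw counts (relative abundance is
#'   computed per sample within each transect-habitat subset).
#' @param candidates Optional tibble (`otu_id`, `transect`, `habitat`)
#'   restricting the screen; defaults to every combination where the OTU
#'   occurs in at least `min_present` samples.
#' @param alpha Screening significance level.
#' @param n_permutations,seed Permutation settings for [mantel()].
#' @param min_present Minimum number of samples with the OTU present.
#' @return A tibble `otu_id`, `transect`, `habitat`, `mantel_r`, `p_value`,
#'   `flagged`; candidates with degenerate (constant) distance structure are
#'   dropped with a message.
#' @export
mantel_screen <- function(table, candidates = NULL, alpha = 0.05,
                          n_permutations = 999, seed = 1L, min_present = 5L) {
  stopifnot(inherits(table, "spatial_otu_table"))
  occ <- otu_occupancy(table)
  if (is.null(candidates)) {
    candidates <- occ[occ$occupancy >= min_present,
                      c("otu_id", "transect", "habitat")]
  } else {
    candidates <- dplyr::semi_join(
      dplyr::left_join(candidates, occ,
                       by = c("otu_id", "transect", "habitat")),
      occ[occ$occupancy >= min_present, ],
      by = c("otu_id", "transect", "habitat")
    )[, c("otu_id", "transect", "habitat")]
  }
  if (nrow(candidates) == 0) {
    return(tibble::tibble(otu_id = character(), transect = character(),
                          habitat = character(), mantel_r = numeric(),
                          p_value = numeric(), flagged = logical()))
  }
  md <- table$samples
  seeds <- derive_seeds(seed, nrow(candidates))
  n_skipped <- 0L
  out <- purrr::map_dfr(seq_len(nrow(candidates)), function(k) {
    cand <- candidates[k, ]
    ids <- md$sample_id[md$transect == cand$transect &
                          md$habitat == cand$habitat]
    sub <- table$abundance[ids, , drop = FALSE]
    tot <- rowSums(sub)
    ids <- ids[tot > 0]
    rel <- sub[tot > 0, cand$otu_id] / tot[tot > 0]
    if (length(ids) < max(3, min_present) || sd(rel) == 0) {
      n_skipped <<- n_skipped + 1L
      return(NULL)
    }
    d1 <- single_otu_bray(rel)
    d2 <- geographic_distance(md[match(ids, md$sample_id), ])
    mt <- mantel(d1, d2, n_permutations = n_permutations, seed = seeds[[k]],
                 alternative = "greater")
    if (mt$degenerate) {
      n_skipped <<- n_skipped + 1L
      return(NULL)
    }
    tibble::tibble(
      otu_id = cand$otu_id, transect = cand$transect, habitat = cand$habitat,
      mantel_r = mt$statistic, p_value = mt$p_value,
      flagged = mt$p_value <= alpha
    )
  })
  if (n_skipped > 0) {
    inform(sprintf("mantel_screen: skipped %d degenerate candidate(s).",
                   n_skipped))
  }
  out
}

# Internal: Bray-Curtis restricted to one OTU; 0 when both abundances are 0.
single_otu_bray <- function(x) {
  n <- length(x)
  num <- abs(outer(x, x, "-"))
  den <- outer(x, x, "+")
  d <- ifelse(den > 0, num / den, 0)
  diag(d) <- 0
  d
}

#' Empirical semivariogram (method of moments)
#'
#' `gamma_hat(h) = (1 / (2 N(h))) * sum((z_i - z_j)^2)` over point pairs
#' whose separation falls in each of `n_bins` equal-width lag bins
#' partitioning `(0, max_lag]`. Bins with fewer than `min_pairs` pairs are
#' dropped; lag centers are the mean pair distance per bin.
#'
#' @param values Numeric vector of the (normalized) abundance at each point.
#' @param coords Data frame with `x`, `y` in meters.
#' @param n_bins Number of lag bins (default 12).
#' @param max_lag Largest lag considered; default half the maximum pairwise
#'   distance.
#' @param min_pairs Minimum pairs per retained bin (default 10).
#' @return An `empirical_variogram` tibble (`lag_center`, `semivariance`,
#'   `pair_count`) with attributes `max_lag` and `sample_variance`.
#' @export
empirical_semivariogram <- function(values, coords, n_bins = 12,
                                    max_lag = NULL, min_pairs = 10) {
  coords <- as.data.frame(coords)
  stopifnot(length(values) == nrow(coords), length(values) >= 2)
  h <- dist(coords[, c("x", "y")])
  gsq <- 0.5 * dist(values)^2
  if (is.null(max_lag)) max_lag <- max(h) / 2
  keep <- h > 0 & h <= max_lag
  hv <- h[keep]
  gv <- gsq[keep]
  bin <- cut(hv, breaks = seq(0, max_lag, length.out = n_bins + 1),
             include.lowest = FALSE)
  counts <- tapply(gv, bin, length)
  counts[is.na(counts)] <- 0
  out <- tibble::tibble(
    lag_center = as.numeric(tapply(hv, bin, mean)),
    semivariance = as.numeric(tapply(gv, bin, mean)),
    pair_count = as.integer(counts)
  )
  out <- out[!is.na(out$lag_center) & out$pair_count >= min_pairs, ]
  if (nrow(out) == 0) {
    abort("Insufficient pairs: every lag bin fell below min_pairs.")
  }
  attr(out, "max_lag") <- max_lag
  attr(out, "sample_variance") <- var(values)
  class(out) <- c("empirical_variogram", class(out))
  out
}

#' Fit an exponential variogram model with zero nugget
#'
#' Weighted least squares fit of `gamma(h) = sill * (1 - exp(-h / a))` to an
#' empirical semivariogram, with weights `pair_count / lag^2` and both
#' parameters box-bounded. The nugget is fixed at zero and the model type at
#' exponential so that fitted range sizes are comparable across OTUs. The
#' reported effective range is `3 * a`, the lag at which the model reaches
#' 95% of its sill.
#'
#' @param emp An [empirical_semivariogram()] result (>= 3 retained bins).
#' @param a_max Upper bound for the range parameter; default `10 * max_lag`
#'   (observed ranges can far exceed the transect extent).
#' @param sill_max Upper bound for the sill; default 10x the largest
#'   empirical semivariance.
#' @return A `variogram_model` list: `model_type`, `nugget` (0), `sill`,
#'   `range_param`, `effective_range`, `sse` (weighted), `converged`.
#' @export
fit_exponential <- function(emp, a_max = NULL, sill_max = NULL) {
  stopifnot(inherits(emp, "empirical_variogram"))
  if (nrow(emp) < 3) abort("Need >= 3 variogram bins to fit the model.")
  h <- emp$lag_center
  g <- emp$semivariance
  w <- emp$pair_count / h^2
  max_lag <- attr(emp, "max_lag") %||% max(h)
  if (is.null(a_max)) a_max <- 10 * max_lag
  if (is.null(sill_max)) sill_max <- max(10 * max(g), 1e-8)
  sill0 <- min(max(attr(emp, "sample_variance") %||% max(g), 1e-8), sill_max)
  a0 <- min(max_lag / 3, a_max)
  dat <- data.frame(h = h, g = g, w = w)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      g ~ sill * (1 - exp(-h / a)), data = dat, weights = w,
      start = list(sill = sill0, a = a0),
      lower = c(1e-9, 1e-9), upper = c(sill_max, a_max),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    # fall back to bounded quasi-Newton on the same weighted objective
    obj <- function(p) sum(w * (g - p[1] * (1 - exp(-h / p[2])))^2)
    op <- optim(c(sill0, a0), obj, method = "L-BFGS-B",
                lower = c(1e-9, 1e-9), upper = c(sill_max, a_max))
    pars <- c(sill = op$par[1], a = op$par[2])
    sse <- op$value
    converged <- op$convergence == 0
  } else {
    pars <- stats::coef(fit)
    sse <- sum(w * stats::resid(fit)^2)
    converged <- fit$convInfo$isConv %||% TRUE
  }
  structure(
    list(
      model_type = "exponential", nugget = 0,
      sill = unname(pars[["sill"]]), range_param = unname(pars[["a"]]),
      effective_range = 3 * unname(pars[["a"]]),
      sse = sse, converged = isTRUE(converged)
    ),
    class = "variogram_model"
  )
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf(
    "<variogram_model: exponential, nugget 0> sill = %.4g, a = %.4g m, effective range = %.4g m (sse %.3g%s)\n",
    x$sill, x$range_param, x$effective_range, x$sse,
    if (x$converged) "" else ", NOT converged"
  ))
  invisible(x)
}

#' @export
tidy.variogram_model <- function(x, ...) {
  tibble::tibble(
    term = c("nugget", "sill", "range_param", "effective_range"),
    estimate = c(x$nugget, x$sill, x$range_param, x$effective_range)
  )
}

#' @export
glance.variogram_model <- function(x, ...) {
  tibble::tibble(sill = x$sill, range_param = x$range_param,
                 effective_range = x$effective_range, sse = x$sse,
                 converged = x$converged)
}

# Model semivariance at lag h.
variogram_gamma <- function(model, h) {
  model$sill * (1 - exp(-h / model$range_param))
}

#' Plot an empirical variogram, optionally with a fitted model
#'
#' @param object An `empirical_variogram`.
#' @param model Optional `variogram_model` overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.empirical_variogram <- function(object, model = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_center,
                                            y = .data$semivariance)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$pair_count), alpha = 0.7) +
    ggplot2::labs(x = "lag (m)", y = "semivariance", size = "pairs") +
    ggplot2::theme_minimal()
  if (!is.null(model)) {
    hh <- seq(0, max(object$lag_center), length.out = 100)
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(lag_center = hh,
                            semivariance = variogram_gamma(model, hh)),
      colour = "firebrick"
    )
  }
  p
}

#' Estimate per-OTU geographic ranges from variogram fits
#'
#' For each (OTU, transect, habitat) flagged by the Mantel screen, builds the
#' empirical semivariogram of the OTU's normalized abundance and fits the
#' zero-nugget exponential model. Generalists present in both habitats of a
#' transect yield one estimate per habitat.
#'
#' @param table A `spatial_otu_table`; normalized values are used as-is,
#'   raw counts are log(1+x) transformed first.
#' @param screen A [mantel_screen()] result (only `flagged` rows are used).
#' @param classifications Optional [classify_otus()] result for labels.
#' @param report `"effective"` (default; range = 3a) or `"parameter"`
#'   (range = a) — which value fills `range_m`.
#' @param n_bins,max_lag,min_pairs Passed to [empirical_semivariogram()].
#' @return A tibble: `otu_id`, `transect`, `habitat`, `label`, `sill`,
#'   `range_param`, `effective_range`, `range_m`, `sse`, `converged`.
#'   Candidates whose variogram or fit fails are dropped with a message.
#' @export
estimate_ranges <- function(table, screen, classifications = NULL,
                            report = c("effective", "parameter"),
                            n_bins = 12, max_lag = NULL, min_pairs = 10) {
  report <- match.arg(report)
  stopifnot(inherits(table, "spatial_otu_table"))
  norm <- normalize_log1p(table)
  flagged <- screen[screen$flagged, ]
  md <- norm$samples
  n_failed <- 0L
  out <- purrr::map_dfr(seq_len(nrow(flagged)), function(k) {
    cand <- flagged[k, ]
    ids <- md$sample_id[md$transect == cand$transect &
                          md$habitat == cand$habitat]
    vals <- norm$abundance[ids, cand$otu_id]
    coords <- md[match(ids, md$sample_id), c("x", "y")]
    est <- tryCatch({
      emp <- empirical_semivariogram(vals, coords, n_bins = n_bins,
                                     max_lag = max_lag, min_pairs = min_pairs)
      fit_exponential(emp)
    }, error = function(e) NULL)
    if (is.null(est)) {
      n_failed <<- n_failed + 1L
      return(NULL)
    }
    tibble::tibble(
      otu_id = cand$otu_id, transect = cand$transect, habitat = cand$habitat,
      sill = est$sill, range_param = est$range_param,
      effective_range = est$effective_range,
      range_m = if (report == "effective") est$effective_range
                else est$range_param,
      sse = est$sse, converged = est$converged
    )
  })
  if (n_failed > 0) {
    inform(sprintf("estimate_ranges: %d candidate(s) failed to fit and were excluded.",
                   n_failed))
  }
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      otu_id = character(), transect = character(), habitat = character(),
      sill = numeric(), range_param = numeric(), effective_range = numeric(),
      range_m = numeric(), sse = numeric(), converged = logical()
    )
  }
  if (!is.null(classifications)) {
    out <- dplyr::left_join(
      out, classifications[, c("otu_id", "transect", "label")],
      by = c("otu_id", "transect")
    )
  } else if (nrow(out) > 0 || !"label" %in% names(out)) {
    out$label <- NA_character_
  }
  out[, c("otu_id", "transect", "habitat", "label", "sill", "range_param",
          "effective_range", "range_m", "sse", "converged")]
}

#' Cull unrealistic range models and flag outliers
#'
#' Mirrors the two-stage model triage of the field protocol: estimates with
#' `range_m < min_range_m` (default 1 m, below the sampling grain) are
#' culled; among the survivors, exceptionally large ranges are flagged as
#' outliers by rule — above the transect diagonal and/or beyond the upper
#' Tukey fence on log range. Returns the annotated estimates plus an audit
#' of counts with `n_remaining = n_total - n_culled - n_outliers`.
#'
#' @param estimates An [estimate_ranges()] tibble (or any tibble with a
#'   `range_m` column).
#' @param min_range_m Culling threshold in meters (default 1).
#' @param outlier_rule `"diagonal"` (default), `"tukey"`, `"both"` (either
#'   rule flags) or `"none"`.
#' @param transect_diagonal Diagonal of the transect box in meters (default
#'   `sqrt(10^2 + 40^2)`).
#' @param tukey_k Fence multiplier on the log-range IQR (default 1.5).
#' @return A `cull_result` list: `estimates` (input plus `culled`, `outlier`
#'   columns) and `audit` (tibble: `n_total`, `n_culled`, `n_outliers`,
#'   `n_remaining`).
#' @export
cull_and_flag <- function(estimates, min_range_m = 1,
                          outlier_rule = c("diagonal", "tukey", "both", "none"),
                          transect_diagonal = sqrt(10^2 + 40^2),
                          tukey_k = 1.5) {
  outlier_rule <- match.arg(outlier_rule)
  est <- tibble::as_tibble(estimates)
  est$culled <- est$range_m < min_range_m
  est$outlier <- FALSE
  surv <- !est$culled
  if (any(surv) && outlier_rule != "none") {
    flag <- rep(FALSE, sum(surv))
    r <- est$range_m[surv]
    if (outlier_rule %in% c("diagonal", "both")) {
      flag <- flag | r > transect_diagonal
    }
    if (outlier_rule %in% c("tukey", "both")) {
      lr <- log(r)
      fence <- quantile(lr, 0.75) + tukey_k * stats::IQR(lr)
      flag <- flag | lr > fence
    }
    est$outlier[surv] <- flag
  }
  audit <- tibble::tibble(
    n_total = nrow(est),
    n_culled = sum(est$culled),
    n_outliers = sum(est$outlier),
    n_remaining = nrow(est) - sum(est$culled) - sum(est$outlier)
  )
  structure(list(estimates = est, audit = audit), class = "cull_result")
}

#' @export
print.cull_result <- function(x, ...) {
  a <- x$audit
  cat(sprintf(
    "<cull_result> %d models: %d culled (< min range), %d outliers, %d remaining\n",
    a$n_total, a$n_culled, a$n_outliers, a$n_remaining
  ))
  invisible(x)
}

#' Compare range sizes between class-habitat groups
#'
#' Pairwise Wilcoxon rank-sum tests on `range_m` across `label:habitat`
#' groups of the surviving (non-culled, non-outlier) estimates, BH-corrected,
#' with group medians and IQRs.
#'
#' @param cull A [cull_and_flag()] result, or an estimates tibble with
#'   `culled`/`outlier` columns (rows flagged either way are excluded).
#' @return As [compare_occupancy()]: list of `comparisons` and `summary`.
#' @export
compare_ranges <- function(cull) {
  est <- if (inherits(cull, "cull_result")) cull$estimates else cull
  est <- est[!est$culled & !est$outlier & !is.na(est$label), ]
  groups <- tibble::tibble(
    group = paste(est$label, est$habitat, sep = ":"),
    range_m = est$range_m
  )
  compare_groups(groups, "range_m")
}
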