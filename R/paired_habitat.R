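#' Same-location cross-habitat dissimilarities
#'
#' One Bray-Curtis value per complete soil/phylloplane pair — the two
#' communities collected at the same geographic point — ordered by
#' `(transect, location_index)`. Locations missing one habitat are skipped
#' with a warning. Singleton OTUs are retained (dissimilarity analysis).
#'
#' @param table A `spatial_otu_table`.
#' @param scope Optional character vector of sample IDs restricting the
#'   analysis (e.g. one transect); default uses every sample.
#' @return A tibble with columns `transect`, `location_index`, `bray_curtis`.
#' @export
observed_pair_dissimilarities <- function(table, scope = NULL) {
  stopifnot(inherits(table, "spatial_otu_table"))
  if (!is.null(scope)) table <- subset_samples(table, scope)
  pairs <- complete_pairs(table)
  if (nrow(pairs) == 0) abort("No complete soil/phylloplane pairs in scope.")
  a <- table$abundance[pairs$sample_1, , drop = FALSE]
  b <- table$abundance[pairs$sample_2, , drop = FALSE]
  bc <- rowSums(abs(a - b)) / (rowSums(a) + rowSums(b))
  tibble::tibble(
    transect = pairs$transect,
    location_index = pairs$location_index,
    bray_curtis = unname(bc)
  )
}

# Internal: one uniform random derangement of 1..n by rejection (n >= 2).
random_derangement <- function(n) {
  if (n < 2) abort("A derangement needs at least 2 elements.")
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

#' Randomized-pairing null dissimilarities
#'
#' The null pairs each soil community with the phylloplane community of a
#' *different* location: each of `n_randomizations` iterations draws a
#' seeded random derangement of the location indices in scope and emits
#' `BC(soil_i, phyllo_perm(i))` for every pair. Same-location pairs never
#' enter the null.
#'
#' @inheritParams observed_pair_dissimilarities
#' @param n_randomizations Number of derangements pooled (default 99).
#' @param seed Integer seed.
#' @return A tibble with columns `iteration`, `transect` (of the soil
#'   sample), `location_index`, `bray_curtis`; `n_pairs * n_randomizations`
#'   rows.
#' @export
randomized_pair_dissimilarities <- function(table, scope = NULL,
                                            n_randomizations = 99, seed = 1L) {
  stopifnot(inherits(table, "spatial_otu_table"))
  if (!is.null(scope)) table <- subset_samples(table, scope)
  pairs <- complete_pairs(table, quiet = TRUE)
  n <- nrow(pairs)
  if (n < 2) abort("Need at least 2 complete pairs to build a derangement null.")
  cross <- cross_bray(
    table$abundance[pairs$sample_1, , drop = FALSE],
    table$abundance[pairs$sample_2, , drop = FALSE]
  )
  perms <- with_seed(seed, {
    purrr::map(seq_len(n_randomizations), ~ random_derangement(n))
  })
  purrr::map_dfr(seq_along(perms), function(it) {
    p <- perms[[it]]
    tibble::tibble(
      iteration = it,
      transect = pairs$transect,
      location_index = pairs$location_index,
      bray_curtis = cross[cbind(seq_len(n), p)]
    )
  })
}

#' Inter-habitat spatial autocorrelation test
#'
#' Tests whether paired soil and phylloplane communities from the same
#' geographic point are more similar than communities from disjunct
#' locations. Observed same-location Bray-Curtis dissimilarities are
#' compared with the randomized-pairing null by a two-sided two-sample
#' t-test; spatial autocorrelation is called when the observed mean is
#' smaller than the randomized mean with `p <= alpha`. Run at the scale of
#' the entire study (randomization unrestricted across transects) and/or per
#' transect (randomization confined within the transect).
#'
#' @param table A `spatial_otu_table` (singletons retained).
#' @param scale `"entire_study"`, `"per_transect"`, or `"both"`.
#' @param n_randomizations Derangements pooled into the null (default 99).
#' @param seed Integer seed.
#' @param alpha Significance level for the autocorrelation call.
#' @param t_variant Passed to [t_test_two_sample()].
#' @return A `paired_habitat_result` tibble, one row per scale, with columns
#'   `scale_label`, `observed_mean_bc`, `randomized_mean_bc`, `t_statistic`,
#'   `df`, `p_value`, `autocorrelated`, `n_pairs`, `n_randomizations`,
#'   `seed`.
#' @export
inter_habitat_test <- function(table,
                               scale = c("both", "entire_study", "per_transect"),
                               n_randomizations = 99, seed = 1L, alpha = 0.05,
                               t_variant = "welch") {
  scale <- match.arg(scale)
  stopifnot(inherits(table, "spatial_otu_table"))
  scopes <- list()
  if (scale %in% c("both", "entire_study")) {
    scopes[["entire_study"]] <- sample_ids(table)
  }
  if (scale %in% c("both", "per_transect")) {
    for (tr in unique(table$samples$transect)) {
      ids <- table$samples$sample_id[table$samples$transect == tr]
      scopes[[paste0("transect:", tr)]] <- ids
    }
  }
  seeds <- derive_seeds(seed, length(scopes))
  out <- purrr::map_dfr(seq_along(scopes), function(i) {
    label <- names(scopes)[[i]]
    obs <- observed_pair_dissimilarities(table, scopes[[i]])
    rand <- randomized_pair_dissimilarities(table, scopes[[i]],
                                            n_randomizations, seeds[[i]])
    tt <- t_test_two_sample(obs$bray_curtis, rand$bray_curtis,
                            variant = t_variant)
    tibble::tibble(
      scale_label = label,
      observed_mean_bc = mean(obs$bray_curtis),
      randomized_mean_bc = mean(rand$bray_curtis),
      t_statistic = tt$statistic,
      df = tt$df,
      p_value = tt$p_value,
      autocorrelated = !isTRUE(tt$degenerate) &&
        mean(obs$bray_curtis) < mean(rand$bray_curtis) &&
        !is.na(tt$p_value) && tt$p_value <= alpha,
      n_pairs = nrow(obs),
      n_randomizations = as.integer(n_randomizations),
      seed = seeds[[i]]
    )
  })
  class(out) <- c("paired_habitat_result", class(out))
  out
}

#' @export
glance.paired_habitat_result <- function(x, ...) {
  tibble::tibble(
    n_scales = nrow(x),
    n_autocorrelated = sum(x$autocorrelated),
    min_p = min(x$p_value, na.rm = TRUE)
  )
}

#' Plot observed vs randomized dissimilarity per scale
#'
#' @param object A `paired_habitat_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.paired_habitat_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object, c("observed_mean_bc", "randomized_mean_bc"),
    names_to = "pairing", values_to = "mean_bc"
  )
  long$pairing <- ifelse(long$pairing == "observed_mean_bc",
                         "observed", "randomized")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$scale_label, y = .data$mean_bc, fill = .data$pairing
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(
      ylim = c(min(long$mean_bc) * 0.98, max(long$mean_bc) * 1.01)
    ) +
    ggplot2::labs(
      x = NULL, y = "mean Bray-Curtis dissimilarity",
      title = "Same-location vs randomized cross-habitat dissimilarity"
    ) +
    ggplot2::theme_minimal()
}
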