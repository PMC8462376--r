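#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum(|x - y|) / sum(x + y)`, 0 for identical profiles and 1 for
#' disjoint ones. Computed on whatever abundance scale the input carries;
#' community-dissimilarity analyses keep singleton OTUs.
#'
#' @param abundance A samples x OTUs numeric matrix (rownames are sample
#'   IDs), or a `spatial_otu_table`.
#' @return A symmetric `dist_matrix` (base matrix with sample IDs as
#'   dimnames) with zero diagonal and entries in \[0, 1\].
#' @examples
#' m <- rbind(a = c(1, 2, 3), b = c(3, 2, 1))
#' bray_curtis(m)[1, 2] # 1/3
#' @export
bray_curtis <- function(abundance) {
  if (inherits(abundance, "spatial_otu_table")) abundance <- abundance$abundance
  abundance <- as.matrix(abundance)
  if (any(abundance < 0)) abort("Bray-Curtis requires non-negative abundances.")
  tot <- rowSums(abundance)
  zero <- which(tot == 0)
  if (length(zero) >= 2) {
    abort(sprintf(
      "Bray-Curtis is undefined between all-zero samples: %s.",
      paste(rownames(abundance)[zero], collapse = ", ")
    ))
  }
  d <- cross_bray(abundance, abundance)
  dimnames(d) <- list(rownames(abundance), rownames(abundance))
  diag(d) <- 0
  class(d) <- c("dist_matrix", class(d))
  d
}

# Internal: Bray-Curtis between every row of A and every row of B.
cross_bray <- function(a, b) {
  sa <- rowSums(a)
  sb <- rowSums(b)
  out <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) {
    num <- colSums(abs(t(b) - a[i, ]))
    den <- sa[[i]] + sb
    out[i, ] <- ifelse(den > 0, num / den, NA_real_)
  }
  out
}

#' Euclidean geographic distance matrix
#'
#' @param coords Data frame with columns `x`, `y` in meters (and optionally
#'   `sample_id` used for labels), or a `spatial_otu_table` (distances between
#'   its samples).
#' @return A symmetric `dist_matrix` of distances in meters.
#' @export
geographic_distance <- function(coords) {
  if (inherits(coords, "spatial_otu_table")) coords <- coords$samples
  coords <- as.data.frame(coords)
  stopifnot(all(c("x", "y") %in% names(coords)))
  if (!all(is.finite(coords$x)) || !all(is.finite(coords$y))) {
    abort("Coordinates must be finite.")
  }
  d <- as.matrix(dist(coords[, c("x", "y")]))
  labs <- coords$sample_id %||% rownames(coords)
  dimnames(d) <- list(labs, labs)
  class(d) <- c("dist_matrix", class(d))
  d
}

# Internal: all permutations of 1..n (n! rows); used by the exact modes.
all_permutations <- function(n) {
  if (n > 8L) abort("Exhaustive enumeration is limited to n <= 8.")
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (pos in seq_len(n)) {
    block <- cbind(
      sub[, seq_len(pos - 1L), drop = FALSE],
      n,
      sub[, seq.int(pos, n - 1L)[seq_len(n - pos)], drop = FALSE]
    )
    out <- rbind(out, block)
  }
  out
}

new_perm_test <- function(statistic, p_value, n_permutations, seed,
                          method, degenerate = FALSE, ...) {
  structure(
    c(
      list(
        statistic = statistic, p_value = p_value,
        n_permutations = n_permutations, seed = seed,
        method = method, degenerate = degenerate
      ),
      list(...)
    ),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test: %s> statistic = %s, p = %s (%s permutations%s)\n",
              x$method,
              format(x$statistic, digits = 4), format(x$p_value, digits = 4),
              if (is.na(x$n_permutations)) "exhaustive" else x$n_permutations,
              if (x$degenerate) ", DEGENERATE" else ""))
  invisible(x)
}

#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    statistic = x$statistic,
    p.value = x$p_value,
    n_permutations = x$n_permutations,
    seed = x$seed,
    degenerate = x$degenerate,
    r_squared = x$r_squared %||% NA_real_
  )
}

# Internal: permanova pseudo-F and R^2 from squared distances and labels.
permanova_stat <- function(d2, groups) {
  n <- nrow(d2)
  g <- length(unique(groups))
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (lev in unique(groups)) {
    idx <- which(groups == lev)
    if (length(idx) > 1) {
      sub <- d2[idx, idx]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ss_between <- ss_total - ss_within
  f <- (ss_between / (g - 1)) / (ss_within / (n - g))
  c(f = f, r2 = ss_between / ss_total)
}

#' Permutational multivariate analysis of variance (permanova)
#'
#' One-factor permanova on a distance matrix via the pseudo-F statistic from
#' the Gower-centered squared-distance decomposition, with a permutation
#' p-value under random relabeling (add-one convention), or exhaustive
#' enumeration of all `n!` relabelings when `exact = TRUE`.
#'
#' @param dist_matrix Symmetric distance matrix with sample labels.
#' @param groups Group label per sample (same order as the matrix), or a
#'   named vector matched by label.
#' @param n_permutations Number of random relabelings (default 999).
#' @param seed Integer seed for the permutation stream.
#' @param exact Enumerate all permutations instead (n <= 8).
#' @return A `perm_test` with fields `statistic` (pseudo-F), `p_value`,
#'   `r_squared`, `df`; `degenerate = TRUE` with `NA` statistic when all
#'   distances are zero.
#' @export
permanova <- function(dist_matrix, groups, n_permutations = 999, seed = 1L,
                      exact = FALSE) {
  d <- as.matrix(dist_matrix)
  n <- nrow(d)
  if (!is.null(names(groups)) && !is.null(rownames(d))) {
    groups <- groups[rownames(d)]
  }
  groups <- as.character(groups)
  stopifnot(length(groups) == n)
  tab <- table(groups)
  g <- length(tab)
  if (g < 2) abort("permanova needs at least 2 groups.")
  if (n - g <= 0) abort("No residual degrees of freedom (n - g <= 0).")
  d2 <- d^2
  if (all(d2 == 0)) {
    return(new_perm_test(NA_real_, NA_real_, NA_integer_, seed, "permanova",
                         degenerate = TRUE, r_squared = NA_real_,
                         df = c(g - 1L, n - g)))
  }
  obs <- permanova_stat(d2, groups)
  eps <- 1e-12
  if (exact) {
    perms <- all_permutations(n)
    f_perm <- apply(perms, 1, function(p) permanova_stat(d2, groups[p])[["f"]])
    p_value <- mean(f_perm >= obs[["f"]] - eps)
    n_perm_out <- NA_integer_
  } else {
    f_perm <- with_seed(seed, {
      vapply(seq_len(n_permutations), function(i) {
        permanova_stat(d2, groups[sample.int(n)])[["f"]]
      }, numeric(1))
    })
    p_value <- (1 + sum(f_perm >= obs[["f"]] - eps)) / (n_permutations + 1)
    n_perm_out <- as.integer(n_permutations)
  }
  new_perm_test(obs[["f"]], p_value, n_perm_out, seed, "permanova",
                r_squared = obs[["r2"]], df = c(g - 1L, n - g))
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper-triangle entries, with significance by
#' permuting the rows/columns of the second matrix. One-sided (`"greater"`,
#' the spatial-autocorrelation screen direction) by default; permutation
#' p-values use the add-one convention, and `exact = TRUE` enumerates all
#' `n!` label permutations.
#'
#' @param d1,d2 Symmetric distance matrices over the same labels in the same
#'   order.
#' @param n_permutations,seed,exact As in [permanova()].
#' @param alternative `"greater"`, `"less"` or `"two_sided"`.
#' @return A `perm_test` with the Mantel `r` as statistic; degenerate (with
#'   `NA` p-value) when either triangle has zero variance.
#' @export
mantel <- function(d1, d2, n_permutations = 999, seed = 1L,
                   alternative = c("greater", "less", "two_sided"),
                   exact = FALSE) {
  alternative <- match.arg(alternative)
  m1 <- as.matrix(d1)
  m2 <- as.matrix(d2)
  stopifnot(nrow(m1) == nrow(m2), ncol(m1) == nrow(m1))
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2))) {
    abort("Mantel requires the same labels in the same order.")
  }
  n <- nrow(m1)
  ut <- upper.tri(m1)
  v1 <- m1[ut]
  if (sd(v1) == 0 || sd(m2[ut]) == 0) {
    return(new_perm_test(NA_real_, NA_real_, NA_integer_, seed, "mantel",
                         degenerate = TRUE))
  }
  stat_for <- function(perm) cor(v1, m2[perm, perm][ut])
  r_obs <- stat_for(seq_len(n))
  eps <- 1e-12
  side_count <- function(r_perm) {
    switch(alternative,
      greater = r_perm >= r_obs - eps,
      less = r_perm <= r_obs + eps,
      two_sided = abs(r_perm) >= abs(r_obs) - eps
    )
  }
  if (exact) {
    perms <- all_permutations(n)
    r_perm <- apply(perms, 1, stat_for)
    p_value <- mean(side_count(r_perm))
    n_perm_out <- NA_integer_
  } else {
    r_perm <- with_seed(seed, {
      vapply(seq_len(n_permutations), function(i) stat_for(sample.int(n)),
             numeric(1))
    })
    p_value <- (1 + sum(side_count(r_perm))) / (n_permutations + 1)
    n_perm_out <- as.integer(n_permutations)
  }
  new_perm_test(r_obs, p_value, n_perm_out, seed, "mantel",
                alternative = alternative)
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Exact by enumeration of all rank assignments when `n_a + n_b <= 12` and
#' there are no ties; otherwise the normal approximation with tie correction
#' and continuity correction. The statistic is the Mann-Whitney U of the
#' first sample.
#'
#' @param a,b Numeric vectors (both nonempty).
#' @return A list with `statistic` (U), `p_value` and `exact` flag.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  na <- length(a)
  nb <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(c(a, b)))
  mu <- na * nb / 2
  if (na + nb <= 12 && !ties) {
    # exact null distribution of U over all C(na+nb, na) rank assignments
    sets <- combn(na + nb, na)
    u_all <- colSums(matrix(seq_len(na + nb)[sets], nrow = na)) -
      na * (na + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-9)
    list(statistic = u, p_value = p, exact = TRUE)
  } else {
    n <- na + nb
    tie_tab <- table(r)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 == 0) return(list(statistic = u, p_value = 1, exact = FALSE))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    list(statistic = u, p_value = min(1, 2 * pnorm(-abs(z))), exact = FALSE)
  }
}

#' Two-sample t-test
#'
#' Welch (default) or pooled-variance two-sided t-test, computed from the
#' standard closed forms; Welch degrees of freedom by Welch-Satterthwaite.
#'
#' @param a,b Numeric vectors of length >= 2.
#' @param variant `"welch"` or `"pooled"`.
#' @return A list with `statistic`, `df`, `p_value`, `mean_a`, `mean_b`, and
#'   a `degenerate` flag set when both samples have zero variance.
#' @export
t_test_two_sample <- function(a, b, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a)
  nb <- length(b)
  va <- var(a)
  vb <- var(b)
  if (va == 0 && vb == 0) {
    return(list(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                mean_a = mean(a), mean_b = mean(b), degenerate = TRUE))
  }
  if (variant == "welch") {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- na + nb - 2
  }
  t_stat <- (mean(a) - mean(b)) / sqrt(se2)
  list(statistic = t_stat, df = df, p_value = 2 * pt(-abs(t_stat), df),
       mean_a = mean(a), mean_b = mean(b), degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; the output preserves the input
#' order, never decreases any p-value, and is idempotent.
#'
#' @param p_values Numeric vector in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  m <- length(p_values)
  if (m == 0) return(numeric(0))
  ord <- order(p_values, decreasing = TRUE)
  adj <- pmin(1, cummin(p_values[ord] * m / seq(m, 1)))
  adj[order(ord)]
}
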