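# Independent oracles used across the suite. These deliberately use the
# plainest possible code paths (double loops, exhaustive enumeration) and
# never call the implementation under test.

oracle_bray_curtis <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sum(abs(mat[i, ] - mat[j, ])) / sum(mat[i, ] + mat[j, ])
    }
  }
  d
}

# All permutations of 1..n as a list (plain recursion, n small).
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in oracle_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(sub, n, after = pos)
    }
  }
  out
}

# Exhaustive permanova p-value from first principles.
oracle_permanova_p <- function(d, groups) {
  stat <- function(grp) {
    n <- nrow(d)
    g <- length(unique(grp))
    d2 <- d^2
    sst <- sum(d2[upper.tri(d2)]) / n
    ssw <- 0
    for (lev in unique(grp)) {
      idx <- which(grp == lev)
      if (length(idx) > 1) {
        sub <- d2[idx, idx]
        ssw <- ssw + sum(sub[upper.tri(sub)]) / length(idx)
      }
    }
    ((sst - ssw) / (g - 1)) / (ssw / (n - g))
  }
  obs <- stat(groups)
  f_all <- vapply(oracle_perms(nrow(d)),
                  function(p) stat(groups[p]), numeric(1))
  mean(f_all >= obs - 1e-12)
}

# Exhaustive one-sided Mantel p-value.
oracle_mantel_p <- function(d1, d2) {
  ut <- upper.tri(d1)
  r_for <- function(p) cor(d1[ut], d2[p, p][ut])
  obs <- r_for(seq_len(nrow(d1)))
  r_all <- vapply(oracle_perms(nrow(d1)), r_for, numeric(1))
  mean(r_all >= obs - 1e-12)
}

# Direct weighted least squares polynomial fit evaluated at x0.
oracle_wls_at <- function(x, y, w, degree, x0) {
  X <- outer(x - x0, 0:degree, `^`)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
  beta[1]
}

# Random small valid spatial OTU table for property tests.
random_table <- function(seed, n_loc = 4, n_otu = 5) {
  withr::with_seed(seed, {
    coords <- data.frame(location_index = 1:n_loc,
                         x = runif(n_loc, 0, 10), y = runif(n_loc, 0, 40))
    md <- do.call(rbind, lapply(c("soil", "phylloplane"), function(h) {
      data.frame(sample_id = paste0("s", 1:n_loc, "_", h), transect = "T1",
                 habitat = h, location_index = 1:n_loc,
                 x = coords$x, y = coords$y)
    }))
    ab <- matrix(rpois(nrow(md) * n_otu, 3), nrow(md), n_otu,
                 dimnames = list(md$sample_id, paste0("otu", 1:n_otu)))
    ab[1, ] <- ab[1, ] + 1 # keep every sample non-empty
    spatial_otu_table(ab, md)
  })
}

# Tiny deterministic table from explicit abundance rows.
toy_table <- function(ab, habitats = c("soil", "phylloplane")) {
  n_loc <- nrow(ab) / 2
  md <- data.frame(
    sample_id = rownames(ab),
    transect = "T1",
    habitat = rep(habitats, each = n_loc),
    location_index = rep(seq_len(n_loc), 2),
    x = rep(seq_len(n_loc), 2), y = 0
  )
  spatial_otu_table(ab, md, habitats = habitats)
}
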