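test_that("bray_curtis matches hand values and the double-loop oracle", {
  m <- rbind(a = c(1, 2, 3), b = c(3, 2, 1), c = c(5, 0, 0), d = c(0, 7, 0))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 4 / 12)
  expect_equal(d["c", "d"], 1) # disjoint supports
  expect_equal(d["a", "a"], 0)
  expect_true(isSymmetric(unclass(d)))

  for (seed in 1:20) {
    mat <- withr::with_seed(seed, matrix(rpois(5 * 7, 4) + 0.0, 5, 7))
    mat[rowSums(mat) == 0, 1] <- 1
    rownames(mat) <- paste0("s", 1:5)
    expect_equal(unclass(bray_curtis(mat)), oracle_bray_curtis(mat),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("bray_curtis rejects a pair of all-zero samples, naming them", {
  m <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 2))
  expect_error(bray_curtis(m), "a, b")
})

test_that("geographic_distance is Euclidean in meters", {
  d <- geographic_distance(data.frame(x = c(0, 3, 0), y = c(0, 4, 0)))
  expect_equal(d[1, 2], 5)
  expect_equal(d[1, 3], 0)
  d2 <- geographic_distance(data.frame(x = c(0, 10), y = c(0, 40)))
  expect_equal(d2[1, 2], sqrt(1700))
})

test_that("permanova matches exhaustive enumeration and vegan on small cases", {
  # 4 samples AABB, tiny within- and unit between-group distances
  d <- matrix(1, 4, 4)
  diag(d) <- 0
  d[1, 2] <- d[2, 1] <- d[3, 4] <- d[4, 3] <- 1e-3
  rownames(d) <- colnames(d) <- paste0("s", 1:4)
  res <- permanova(d, c("A", "A", "B", "B"), exact = TRUE)
  expect_equal(res$p_value, 8 / 24)
  expect_equal(res$p_value, oracle_permanova_p(d, c("A", "A", "B", "B")))

  # random 6-sample matrices: exact mode equals the enumeration oracle
  for (seed in c(5, 6)) {
    pts <- withr::with_seed(seed, matrix(runif(12), 6, 2))
    dd <- as.matrix(dist(pts))
    grp <- c("A", "A", "A", "B", "B", "B")
    expect_equal(permanova(dd, grp, exact = TRUE)$p_value,
                 oracle_permanova_p(dd, grp))
  }

  # statistic and R^2 agree with vegan::adonis2 on a larger random case
  skip_if_not_installed("vegan")
  mat <- withr::with_seed(9, matrix(rpois(20 * 8, 5) + 0.0, 20, 8))
  rownames(mat) <- paste0("s", 1:20)
  grp <- rep(c("A", "B"), each = 10)
  d20 <- bray_curtis(mat)
  mine <- permanova(d20, grp, n_permutations = 199, seed = 3)
  ref <- vegan::adonis2(stats::as.dist(d20) ~ grp, permutations = 199)
  expect_equal(mine$statistic, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$r_squared, ref$R2[1], tolerance = 1e-10)
})

test_that("permanova flags the all-identical degenerate case", {
  d <- matrix(0, 4, 4)
  res <- permanova(d, c("A", "A", "B", "B"))
  expect_true(res$degenerate)
  expect_true(is.na(res$statistic))
})

test_that("permanova p is invariant to sample reordering", {
  pts <- withr::with_seed(21, matrix(runif(12), 6, 2))
  d <- as.matrix(dist(pts))
  grp <- c("A", "B", "A", "B", "A", "B")
  p1 <- permanova(d, grp, exact = TRUE)$p_value
  ord <- c(3, 1, 5, 2, 6, 4)
  p2 <- permanova(d[ord, ord], grp[ord], exact = TRUE)$p_value
  expect_equal(p1, p2)
})

test_that("mantel matches enumeration, handles perfect and affine correlation", {
  pts <- withr::with_seed(31, matrix(runif(8), 4, 2))
  d1 <- as.matrix(dist(pts))
  vals <- withr::with_seed(32, runif(4))
  d2 <- as.matrix(dist(vals))
  expect_equal(mantel(d1, d2, exact = TRUE)$p_value, oracle_mantel_p(d1, d2))

  pts5 <- withr::with_seed(33, matrix(runif(10), 5, 2))
  d1b <- as.matrix(dist(pts5))
  d2b <- as.matrix(dist(withr::with_seed(34, runif(5))))
  expect_equal(mantel(d1b, d2b, exact = TRUE)$p_value,
               oracle_mantel_p(d1b, d2b))

  # identical matrices: r = 1, minimal add-one p (n large enough that no
  # sampled label permutation reproduces r = 1)
  d_big <- as.matrix(dist(withr::with_seed(35, matrix(runif(20), 10, 2))))
  res <- mantel(d_big, d_big, n_permutations = 99, seed = 1)
  expect_equal(res$statistic, 1)
  expect_equal(res$p_value, 1 / 100)
  # positive affine transform leaves r = 1
  expect_equal(mantel(d1, 2 * d1 + 0.3, n_permutations = 9, seed = 1)$statistic, 1)
})

test_that("mantel statistic agrees with vegan and degenerates on constant input", {
  skip_if_not_installed("vegan")
  pts <- withr::with_seed(41, matrix(runif(20), 10, 2))
  d1 <- as.matrix(dist(pts))
  d2 <- as.matrix(dist(withr::with_seed(42, runif(10))))
  mine <- mantel(d1, d2, n_permutations = 99, seed = 5)
  ref <- vegan::mantel(d1, d2, permutations = 99)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)

  expect_true(mantel(d1, matrix(1, 10, 10) - diag(10))$degenerate)
})

test_that("permutation tests are bit-reproducible given a seed", {
  pts <- withr::with_seed(51, matrix(runif(16), 8, 2))
  d <- as.matrix(dist(pts))
  grp <- rep(c("A", "B"), 4)
  expect_identical(permanova(d, grp, n_permutations = 99, seed = 7)$p_value,
                   permanova(d, grp, n_permutations = 99, seed = 7)$p_value)
  d2 <- as.matrix(dist(withr::with_seed(52, runif(8))))
  expect_identical(mantel(d, d2, n_permutations = 99, seed = 7)$p_value,
                   mantel(d, d2, n_permutations = 99, seed = 7)$p_value)
})

test_that("wilcoxon rank-sum: exact enumeration and approximation behave", {
  w <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_true(w$exact)
  expect_equal(w$p_value, 2 / 6)

  w2 <- wilcoxon_rank_sum(1:10, 11:20)
  expect_false(w2$exact) # n = 20 > exact cutoff
  ref <- stats::wilcox.test(1:10, 11:20, exact = TRUE)
  # exact p for a complete shift is 2 / C(20,10)
  expect_equal(ref$p.value, 2 / choose(20, 10))

  # identical small samples sit at the null center
  w3 <- wilcoxon_rank_sum(c(1, 3, 5), c(1, 3, 5))
  expect_equal(w3$statistic, 4.5)
  expect_gt(w3$p_value, 0.9)

  # exact mode agrees with wilcox.test on tie-free small samples
  for (seed in c(61, 62, 63)) {
    ab <- withr::with_seed(seed, sample(1:100, 10))
    a <- ab[1:5]
    b <- ab[6:10]
    expect_equal(wilcoxon_rank_sum(a, b)$p_value,
                 stats::wilcox.test(a, b, exact = TRUE)$p.value)
  }
  # approximate mode agrees with wilcox.test's corrected approximation
  a <- withr::with_seed(64, rpois(15, 4))
  b <- withr::with_seed(65, rpois(18, 6))
  expect_equal(wilcoxon_rank_sum(a, b)$p_value,
               stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("two-sample t-test matches closed forms and stats::t.test", {
  a <- c(0, 0, 1, 1)
  b <- c(1, 1, 2, 2)
  res <- t_test_two_sample(a, b, variant = "pooled")
  # pooled: sp2 = 1/3, se = sqrt(1/3 * 1/2), t = -1 / se
  expect_equal(res$statistic, -1 / sqrt(1 / 3 * 0.5))
  expect_equal(res$p_value, stats::t.test(a, b, var.equal = TRUE)$p.value)

  x <- withr::with_seed(71, rnorm(12))
  y <- withr::with_seed(72, rnorm(20, sd = 3))
  w <- t_test_two_sample(x, y)
  ref <- stats::t.test(x, y)
  expect_equal(w$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-12)

  same <- t_test_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_true(t_test_two_sample(c(1, 1), c(2, 2))$degenerate)
})

test_that("t-test holds its nominal type-I error", {
  rejections <- vapply(1:400, function(seed) {
    xy <- withr::with_seed(seed + 4000, rnorm(100))
    t_test_two_sample(xy[1:50], xy[51:100])$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.02)
  expect_lte(mean(rejections), 0.08)
})

test_that("benjamini_hochberg reproduces the step-up rule and its invariants", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")

  for (seed in c(81, 82)) {
    p <- withr::with_seed(seed, runif(23))
    adj <- benjamini_hochberg(p)
    expect_equal(adj, stats::p.adjust(p, method = "BH"))
    expect_true(all(adj >= p))
    # monotone: sorting order of adjusted values follows the raw order
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})
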