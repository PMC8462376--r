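test_that("empirical semivariogram matches the method-of-moments estimator", {
  # two points, values 0 and 2, one bin: gamma = (1/2) * (2)^2 / 1 = 2
  emp <- empirical_semivariogram(c(0, 2), data.frame(x = c(0, 1), y = c(0, 0)),
                                 n_bins = 1, max_lag = 2, min_pairs = 1)
  expect_equal(emp$semivariance, 2)
  expect_equal(emp$pair_count, 1L)
  expect_equal(emp$lag_center, 1)

  # constant field: gamma = 0 in every bin
  g <- expand.grid(x = 0:5, y = 0:5)
  emp0 <- empirical_semivariogram(rep(4, 36), g, n_bins = 5, min_pairs = 5)
  expect_true(all(emp0$semivariance == 0))

  # i.i.d. values on a dense grid: pure nugget, gamma ~ sigma^2 at all lags
  g2 <- expand.grid(x = 0:14, y = 0:14)
  z <- withr::with_seed(4, rnorm(225, sd = 2))
  emp_n <- empirical_semivariogram(z, g2, n_bins = 8, min_pairs = 20)
  expect_lt(max(abs(emp_n$semivariance - 4) / 4), 0.25)

  expect_error(
    empirical_semivariogram(c(1, 2), data.frame(x = c(0, 5), y = c(0, 0)),
                            n_bins = 3, max_lag = 1, min_pairs = 1),
    "Insufficient pairs"
  )
})

test_that("noiseless exponential bins are recovered essentially exactly", {
  h <- 1:10
  emp <- tibble::tibble(
    lag_center = as.numeric(h),
    semivariance = 2 * (1 - exp(-h / 3)),
    pair_count = rep(50L, 10)
  )
  attr(emp, "max_lag") <- 10
  attr(emp, "sample_variance") <- 1.8
  class(emp) <- c("empirical_variogram", class(emp))
  fit <- fit_exponential(emp)
  expect_true(fit$converged)
  expect_equal(fit$sill, 2, tolerance = 1e-6)
  expect_equal(fit$range_param, 3, tolerance = 1e-6)
  expect_lt(fit$sse, 1e-10)
  expect_equal(fit$effective_range, 3 * fit$range_param)
  # closed-form checkpoints of the fitted curve
  expect_equal(mycospat:::variogram_gamma(fit, fit$range_param),
               fit$sill * (1 - exp(-1)), tolerance = 1e-6)
  g_eff <- mycospat:::variogram_gamma(fit, fit$effective_range)
  expect_equal(g_eff / fit$sill, 1 - exp(-3), tolerance = 1e-6)
  expect_gt(g_eff / fit$sill, 0.95) # 1 - e^-3 = 0.9502
})

test_that("mantel screen flags deterministic gradients and skips degenerates", {
  md <- data.frame(
    sample_id = sprintf("s%02d", 1:36), transect = "T1", habitat = "soil",
    location_index = 1:36,
    x = rep(seq(0, 10, length.out = 6), 6),
    y = rep(seq(0, 40, length.out = 6), each = 6)
  )
  dist_corner <- sqrt(md$x^2 + md$y^2)
  ab <- cbind(
    grad = round(100 / (1 + dist_corner)), # decays with distance from corner
    flat = rep(5, 36),
    absent = rep(0, 36),
    noise = withr::with_seed(10, rpois(36, 5))
  )
  rownames(ab) <- md$sample_id
  tab <- spatial_otu_table(ab, md)
  res <- suppressMessages(
    mantel_screen(tab, alpha = 0.05, n_permutations = 199, seed = 2)
  )
  expect_true(res$flagged[res$otu_id == "grad"])
  expect_false("absent" %in% res$otu_id) # skipped, nothing to screen

  # constant relative abundance is degenerate and skipped
  ab_flat <- cbind(c1 = rep(5, 36), c2 = rep(5, 36))
  rownames(ab_flat) <- md$sample_id
  tab_flat <- spatial_otu_table(ab_flat, md)
  res_flat <- suppressMessages(
    mantel_screen(tab_flat, n_permutations = 49, seed = 1)
  )
  expect_equal(nrow(res_flat), 0)
})

test_that("mantel screen size is near alpha under spatial independence", {
  md <- data.frame(
    sample_id = sprintf("s%02d", 1:36), transect = "T1", habitat = "soil",
    location_index = 1:36,
    x = rep(seq(0, 10, length.out = 6), 6),
    y = rep(seq(0, 40, length.out = 6), each = 6)
  )
  n_otu <- 150
  ab <- withr::with_seed(77, matrix(rpois(36 * n_otu, 6), 36, n_otu))
  rownames(ab) <- md$sample_id
  colnames(ab) <- sprintf("otu%03d", seq_len(n_otu))
  tab <- spatial_otu_table(ab, md)
  res <- suppressMessages(
    mantel_screen(tab, alpha = 0.05, n_permutations = 199, seed = 3)
  )
  # binomial 99% envelope around 0.05 for ~150 independent screens
  expect_lt(mean(res$flagged), 0.05 + 2.6 * sqrt(0.05 * 0.95 / nrow(res)))
})

test_that("estimate_ranges recovers simulated effective ranges on a dense grid", {
  g <- expand.grid(x = seq(0, 19), y = seq(0, 19))
  true_eff <- 6
  recovered <- vapply(1:12, function(seed) {
    z <- simulate_gaussian_random_field(g, sill = 1, range_param = true_eff / 3,
                                        seed = 300 + seed)
    emp <- empirical_semivariogram(z, g, n_bins = 12, min_pairs = 10)
    fit_exponential(emp)$effective_range
  }, numeric(1))
  expect_lt(abs(median(recovered) - true_eff) / true_eff, 0.3)
})

test_that("estimate_ranges honours the screen and emits per-habitat estimates", {
  params <- synthetic_params(design = study_design(n_transects = 1),
                             n_generalists = 6, n_soil_specialists = 4,
                             n_phyllo_specialists = 4, coupling_rho = 0.8,
                             seed = 41)
  tab <- simulate_study(params)$table
  filt <- remove_singletons(tab)
  cl <- classify_otus(filt)
  screen <- suppressMessages(
    mantel_screen(filt, alpha = 0.4, n_permutations = 99, seed = 4)
  )
  est <- suppressMessages(estimate_ranges(filt, screen, cl, min_pairs = 5))
  expect_true(all(est$otu_id %in% screen$otu_id[screen$flagged]))
  # generalist screened in both habitats of the transect -> 2 estimates
  counts <- table(paste(est$otu_id, est$transect))
  flagged_both <- dplyr::count(screen[screen$flagged, ],
                               .data$otu_id, .data$transect)
  both <- flagged_both[flagged_both$n == 2, ]
  if (nrow(both) > 0) {
    key <- paste(both$otu_id[1], both$transect[1])
    expect_equal(unname(counts[key]), 2)
  }
  # OTUs failing the screen never get an estimate
  unflagged <- screen[!screen$flagged, ]
  if (nrow(unflagged) > 0) {
    expect_false(any(paste(est$otu_id, est$habitat) %in%
                       paste(unflagged$otu_id, unflagged$habitat) &
                       est$otu_id %in% unflagged$otu_id[1]))
  }
})

test_that("pure-nugget fields mostly yield sub-threshold or failed fits", {
  g <- expand.grid(x = seq(0, 19), y = seq(0, 19))
  small_or_failed <- vapply(1:20, function(seed) {
    z <- withr::with_seed(seed + 600, rnorm(400))
    emp <- empirical_semivariogram(z, g, n_bins = 12, min_pairs = 10)
    fit <- fit_exponential(emp)
    !fit$converged || fit$range_param < 1
  }, logical(1))
  expect_gte(mean(small_or_failed), 0.8)
})

test_that("cull_and_flag reproduces the audit arithmetic and the outlier rule", {
  # constructed estimates reproducing the published audit counts
  est <- tibble::tibble(
    otu_id = sprintf("otu%04d", 1:1060),
    transect = "T1", habitat = "soil", label = "generalist",
    range_m = c(runif(515, 0.05, 0.99), # culled: < 1 m
                runif(539, 1.5, 30),    # retained
                runif(6, 100, 1000))    # outliers: beyond the diagonal
  )
  res <- cull_and_flag(est, min_range_m = 1, outlier_rule = "diagonal")
  expect_equal(res$audit$n_total, 1060)
  expect_equal(res$audit$n_culled, 515)
  expect_equal(res$audit$n_outliers, 6)
  expect_equal(res$audit$n_remaining, 539)

  # nothing removed when all ranges are in the acceptable band
  clean <- tibble::tibble(range_m = runif(50, 2, 30))
  res2 <- cull_and_flag(clean, outlier_rule = "diagonal")
  expect_equal(res2$audit$n_remaining, 50)

  # a range beyond the transect diagonal (~41.23 m) is an outlier
  one <- cull_and_flag(tibble::tibble(range_m = c(5, 42)),
                       outlier_rule = "diagonal")
  expect_equal(one$estimates$outlier, c(FALSE, TRUE))
  # culling wins over the outlier rule
  expect_true(all(!one$estimates$culled | !one$estimates$outlier))
})

test_that("compare_ranges is calibrated under the null and powered under separation", {
  null_rej <- vapply(1:60, function(seed) {
    vals <- withr::with_seed(seed + 900, rlnorm(60, log(3), 0.4))
    est <- tibble::tibble(
      otu_id = as.character(1:60), transect = "T1",
      habitat = rep(c("soil", "phylloplane"), each = 30),
      label = "generalist", range_m = vals,
      culled = FALSE, outlier = FALSE
    )
    cmp <- compare_ranges(est)
    cmp$comparisons$p_adjusted[1] < 0.05
  }, logical(1))
  expect_lte(mean(null_rej), 0.1)

  sep <- tibble::tibble(
    otu_id = as.character(1:80), transect = "T1",
    habitat = rep(c("soil", "phylloplane"), each = 40),
    label = "generalist",
    range_m = c(withr::with_seed(1, rlnorm(40, log(2), 0.3)),
                withr::with_seed(2, rlnorm(40, log(8), 0.3))),
    culled = FALSE, outlier = FALSE
  )
  expect_lt(compare_ranges(sep)$comparisons$p_adjusted[1], 0.001)

  lone <- sep[sep$habitat == "soil", ]
  expect_equal(nrow(compare_ranges(lone)$comparisons), 0)
})
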