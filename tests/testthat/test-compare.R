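test_that("tuning correlation behaves like Pearson r with exclusions", {
  x <- c(1, 2, 3, 4)
  expect_equal(tuning_correlation(x, x), 1)
  expect_equal(tuning_correlation(x, 5 - x), -1)
  expect_equal(tuning_correlation(x, c(2, 4, 5, 9)), 0.9647638, tolerance = 1e-6)
  expect_true(is.na(tuning_correlation(rep(1, 4), x)))
  expect_error(tuning_correlation(c(1, 2), c(1, 2)))
})

test_that("correlation distributions pool inputs and report exclusions", {
  out <- c(1, 3, 2, 5)
  inputs <- rbind(out, out * 2 + 1, rep(4, 4))
  cd <- correlation_distribution(inputs, out)
  expect_equal(cd$r[1:2], c(1, 1))
  expect_true(is.na(cd$r[3]))
  expect_equal(cd$n_excluded, 1)
  expect_equal(cd$mean_r, 1)
})

test_that("KL divergence on pseudocounted histograms is finite and exact", {
  expect_equal(kl_divergence(c(0.75, 0.25), c(0.5, 0.5)),
               0.75 * log(1.5) + 0.25 * log(0.5), tolerance = 1e-12)
  p <- correlation_histogram(runif(50, -1, 1))
  expect_equal(sum(p), 1)
  expect_equal(length(p), 40)
  expect_equal(kl_divergence(p, p), 0)
  # extreme, disjoint samples still give a finite divergence
  q <- correlation_histogram(rep(0.99, 30))
  r <- correlation_histogram(rep(-0.99, 30))
  expect_true(is.finite(kl_divergence(q, r)))
  expect_gt(kl_divergence(q, r), 0)
  expect_error(kl_divergence(c(0.5, 0.5), c(0.3, 0.3, 0.4)))
})

test_that("model identification by KL divergence is self-consistent", {
  hom <- comparison_runs("homogeneous")
  het <- comparison_runs("heterogeneous")
  ref_hom <- correlation_histogram(hom$per_synapse$r)
  ref_het <- correlation_histogram(het$per_synapse$r)
  # per heterogeneous cell: own-model divergence below homogeneous divergence
  cells <- split(het$per_synapse$r,
                 interaction(het$per_synapse$run, het$per_synapse$cell))
  closer <- vapply(cells, function(r) {
    p <- correlation_histogram(r)
    kl_divergence(p, ref_het) < kl_divergence(p, ref_hom)
  }, logical(1))
  expect_gt(mean(closer), 0.9)
  # ranking is robust across the stated range of bin sizes
  for (bw in c(0.001, 0.01, 0.05, 0.1, 0.2)) {
    p <- correlation_histogram(het$per_synapse$r, bin_width = bw)
    qh <- correlation_histogram(hom$per_synapse$r, bin_width = bw)
    expect_gt(kl_divergence(p, qh), kl_divergence(p, p))
  }
})

test_that("homogeneous readouts collect far more co-tuned inputs than heterogeneous", {
  hom <- comparison_runs("homogeneous")
  het <- comparison_runs("heterogeneous")
  pooled_gap <- median(hom$per_synapse$r, na.rm = TRUE) -
    median(het$per_synapse$r, na.rm = TRUE)
  expect_gt(pooled_gap, 0.2)
  # the gap holds in every seeded replicate
  mr <- function(x) tapply(x$per_synapse$r, x$per_synapse$run, median,
                           na.rm = TRUE)
  expect_true(all(mr(hom) - mr(het) > 0.2))
  # both models show positively biased correlation distributions
  expect_gt(median(hom$per_synapse$r, na.rm = TRUE), 0)
  expect_gt(median(het$per_synapse$r, na.rm = TRUE), 0)
})

test_that("PCA slope recovers exact lines and vanishes for isotropic clouds", {
  x <- seq(0, 1, length.out = 30)
  sl <- pca_slope_bootstrap(x, x, n_boot = 200, seed = 1)
  expect_equal(sl$slope, 1, tolerance = 1e-10)
  expect_lt(sl$se, 1e-10)
  sl <- pca_slope_bootstrap(x, 2 * x + 1, n_boot = 200, seed = 1)
  expect_equal(sl$slope, 2, tolerance = 1e-10)
  set.seed(2)
  sl <- pca_slope_bootstrap(rnorm(1000), rnorm(1000), n_boot = 300, seed = 3)
  expect_lt(abs(sl$slope), 3 * sl$se + 0.15)
  expect_error(pca_slope_bootstrap(rep(1, 5), rep(2, 5)))
})

test_that("trial variability splits by orientation only under rate scaling", {
  K <- 8
  grid <- stimulus_grid(K)
  n <- 60
  set.seed(4)
  prefs <- sample(seq_len(K), n, replace = TRUE)
  tun <- vapply(seq_len(n), function(s) {
    0.2 + 5 * exp(-orientation_diff(grid, grid[prefs[s]])^2 / (2 * 20^2))
  }, numeric(K))
  # zero noise: both medians are zero
  arr0 <- array(NA_real_, dim = c(12, K, n))
  for (s in seq_len(n)) arr0[, , s] <- matrix(tun[, s], 12, K, byrow = TRUE)
  vb0 <- variability_by_orientation(arr0 + 1e-15, grid, preferred_index = prefs)
  expect_equal(unname(vb0$summary[c("pref_median", "null_median")]), c(0, 0),
               tolerance = 1e-9)
  # flat additive noise: null and preferred variability agree (control)
  arr_flat <- arr0 + array(rnorm(12 * K * n, 0, 0.4), dim = c(12, K, n))
  vbf <- variability_by_orientation(arr_flat, grid, preferred_index = prefs)
  expect_lt(abs(vbf$summary[["null_median"]] - vbf$summary[["pref_median"]]),
            0.03)
  # Poisson-like (variance = rate) noise: null quieter than preferred
  sd_arr <- array(NA_real_, dim = c(12, K, n))
  for (s in seq_len(n)) sd_arr[, , s] <- matrix(sqrt(tun[, s]), 12, K, byrow = TRUE)
  arr_rate <- arr0 + array(rnorm(12 * K * n), dim = c(12, K, n)) * sd_arr
  vbr <- variability_by_orientation(arr_rate, grid, preferred_index = prefs)
  expect_lt(vbr$summary[["null_median"]], vbr$summary[["pref_median"]])
  expect_lt(vbr$test$p.value, 0.01)
})
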