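test_that("spine generator reproduces its own ground truth in clean limits", {
  # no noise, no contamination: trial averages equal the generating tuning
  ds <- suppressMessages(generate_spine_dataset(
    n_spines = 6, n_trials = 8, noise_sd = 0,
    contamination_range = c(0, 0), seed = 1))
  for (s in 1:6) {
    gt <- ds$ground_truth
    tun <- gt$baseline[s] + gt$amplitude[s] *
      exp(-orientation_diff(ds$stimulus_grid, gt$pref_deg[s])^2 /
            (2 * gt$width_deg[s]^2))
    expect_equal(colMeans(ds$responses[, , s]), tun, tolerance = 1e-12)
  }
  # pure contamination, zero amplitude: spine equals the dendrite signal
  ds <- suppressMessages(generate_spine_dataset(
    n_spines = 3, n_trials = 8, noise_sd = 0,
    amplitude_lognormal = c(meanlog = -Inf, sdlog = 0),
    baseline = 0, contamination_range = c(1, 1), seed = 2))
  expect_equal(ds$responses[, , 2], ds$dendrite, tolerance = 1e-12)
  # default dataset is sized like an imaged cell
  ds <- generate_spine_dataset(seed = 3)
  expect_equal(dim(ds$responses), c(10, 8, 159))
  expect_equal(nrow(ds$blank), 40)
})

test_that("bAP subtraction recovers the contamination scale", {
  expect_equal(subtract_bap(c(1, 2, 3), c(0, 0, 0))$scale, 0)
  expect_equal(subtract_bap(c(1, 2, 3), c(0, 0, 0))$corrected, c(1, 2, 3))
  d <- sin(seq(0, 6, length.out = 60))
  out <- subtract_bap(0.7 * d, d)
  expect_equal(out$scale, 0.7, tolerance = 1e-10)
  expect_equal(max(abs(out$corrected)), 0, tolerance = 1e-10)
  # negative coupling clips to zero
  expect_equal(subtract_bap(-0.5 * d, d)$scale, 0)
  # recovery under tuning + noise at SNR >= 3 stays within +/- 0.1:
  # spine = tuning + 0.5 dendrite + noise, spine amplitude 3x its noise
  grid <- stimulus_grid(8)
  set.seed(4)
  ok <- replicate(60, {
    pref <- runif(1, -90, 90)
    tun <- 0.3 * exp(-orientation_diff(grid, pref)^2 / (2 * 25^2))
    dend <- matrix(exp(-orientation_diff(grid, 0)^2 / (2 * 30^2)),
                   10, 8, byrow = TRUE) + rnorm(80, 0, 0.25)
    spine <- matrix(tun, 10, 8, byrow = TRUE) + 0.5 * dend + rnorm(80, 0, 0.1)
    abs(subtract_bap(spine, dend)$scale - 0.5) <= 0.1
  })
  expect_gt(mean(ok), 0.9)
})

test_that("inclusion filter rejects silent and dendrite-coupled spines", {
  # a dataset of three constructed spines: strong/clean, silent, dendrite copy
  base <- suppressMessages(generate_spine_dataset(
    n_spines = 3, n_trials = 10, noise_sd = 0.1,
    amplitude_lognormal = c(meanlog = log(2), sdlog = 0),
    contamination_range = c(0, 0), seed = 5))
  ds <- base
  set.seed(6)
  # spine 1: strong, clean, and orthogonal to the soma so its visually driven
  # trace is genuinely independent of the dendrite
  tun1 <- 2 * exp(-orientation_diff(ds$stimulus_grid, 90)^2 / (2 * 25^2))
  ds$responses[, , 1] <- matrix(tun1, 10, 8, byrow = TRUE) +
    rnorm(80, 0, 0.1)
  ds$responses[, , 2] <- matrix(rnorm(80, 0, 0.1), 10, 8)   # no visual drive
  ds$responses[, , 3] <- ds$dendrite                         # pure bAP copy
  qc <- spine_inclusion_filter(ds)
  expect_true(qc$pass[1])
  expect_false(qc$pass_snr[2])
  expect_match(qc$reason[2], "low_snr")
  expect_false(qc$pass[3])
  expect_true(all(qc$pass == (qc$pass_snr & qc$pass_cor)))
})

test_that("the dendrite-copy spine fails on correlation before subtraction kicks in", {
  # contamination 1 with a real tuned component: Spearman r with dendrite
  # stays high when subtraction cannot fully separate the signals
  ds <- suppressMessages(generate_spine_dataset(
    n_spines = 2, n_trials = 10, noise_sd = 0,
    amplitude_lognormal = c(meanlog = -Inf, sdlog = 0), baseline = 0,
    contamination_range = c(1, 1), seed = 7))
  ds$responses[, , 1] <- ds$dendrite  # exact copy, no noise
  qc <- spine_inclusion_filter(ds)
  # after perfect subtraction the corrected trace is flat: indeterminate or
  # low SNR, but never a pass
  expect_false(any(qc$pass))
})

test_that("Gaussian tuning fit recovers parameters and flags degeneracy", {
  grid <- stimulus_grid(8)
  y <- 0.2 + 1.5 * exp(-orientation_diff(grid, 30)^2 / (2 * 25^2))
  fit <- fit_tuning_gaussian(y, grid)
  expect_true(fit$converged)
  expect_lt(abs(orientation_diff(fit$pref_deg, 30)), 0.5)
  expect_equal(fit$amplitude, 1.5, tolerance = 1e-3)
  expect_equal(fit$width_deg, 25, tolerance = 0.1)
  # constant responses: degenerate, not converged
  fit <- fit_tuning_gaussian(rep(2, 8), grid)
  expect_false(fit$converged)
  expect_equal(fit$amplitude, 0)
  expect_error(fit_tuning_gaussian(c(1, 2, 3), c(-90, 0, 45)))
})

test_that("preferred-orientation recovery is unbiased under symmetric noise", {
  grid <- stimulus_grid(8)
  set.seed(8)
  err <- replicate(120, {
    pref <- runif(1, -90, 90)
    tun <- 0.1 + exp(-orientation_diff(grid, pref)^2 / (2 * 28^2))
    resp <- matrix(rep(tun, each = 10), 10, 8) + rnorm(80, 0, 1 / 3)
    fit <- fit_tuning_gaussian(resp, grid)
    d2 <- (fit$pref_deg - pref) * 2 * pi / 180
    atan2(sin(d2), cos(d2)) / 2 * 180 / pi  # signed wrapped error
  })
  expect_lt(abs(median(err)), 2)
})

test_that("vector strength measures selectivity on the orientation circle", {
  grid <- stimulus_grid(4)
  expect_equal(vector_strength(c(0, 0, 3, 0), grid), 1)
  expect_equal(vector_strength(rep(2, 4), grid), 0, tolerance = 1e-12)
  expect_equal(vector_strength(c(2, 1, 0, 1), c(-90, -45, 0, 45)), 0.5)
  # invariant to uniform scaling
  r <- c(0.2, 0.9, 2.1, 0.4)
  expect_equal(vector_strength(r, grid), vector_strength(10 * r, grid))
  expect_warning(v <- vector_strength(c(-0.1, 1, 0, 0), grid), "floored")
  expect_error(vector_strength(c(0, 0, 0, 0), grid))
})

test_that("peak normalization gives every spine equal weight", {
  set.seed(9)
  resp <- matrix(rep(c(1, 3, 8, 2), each = 6), 6, 4) + rnorm(24, 0, 0.1)
  norm <- normalize_spine_responses(resp)
  expect_equal(max(colMeans(norm)), 1)
  # two spines with identical shape but different amplitude normalize alike
  expect_equal(normalize_spine_responses(5 * resp), norm,
               ignore_attr = TRUE)
  # normalization commutes with trial averaging for the mean curve
  expect_equal(colMeans(norm), colMeans(resp) / max(colMeans(resp)))
  expect_error(normalize_spine_responses(matrix(-1, 3, 4)))
})
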