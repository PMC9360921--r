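test_that("analytic weights solve Q w = f exactly and reduce to SNR", {
  for (kind in c("homogeneous", "heterogeneous")) {
    pop <- small_population(60, kind, 0.25, seed = 9)
    w <- derive_weights(pop)
    resid <- pop$covariance %*% t(w$weights) - t(pop$mean_response)
    expect_lt(max(abs(resid)) / max(abs(pop$mean_response)), 1e-8)
  }
  # identity covariance: weights equal the tuning curves
  grid <- stimulus_grid(4)
  fm <- rbind(c(1, 2), c(2, 1), c(3, 3), c(1, 4))
  pop <- manual_population(fm, diag(2), grid)
  w <- derive_weights(pop)
  expect_equal(w$weights, fm, tolerance = 1e-12)
  # diagonal covariance: elementwise mean over variance
  pop <- manual_population(fm, diag(c(2, 4)), grid)
  w <- derive_weights(pop)
  expect_equal(w$weights, fm %*% diag(1 / c(2, 4)), tolerance = 1e-12)
})

test_that("hand-solved two-neuron decoder weights and offsets", {
  grid <- c(-45, 45)
  fm <- rbind(c(4, 2), c(2, 4))
  pop <- manual_population(fm, diag(c(2, 1)), grid)
  w <- derive_weights(pop)  # uniform prior over K = 2
  expect_equal(w$weights[1, ], c(2, 2), tolerance = 1e-12)
  expect_equal(w$offsets[1], -6 - log(2), tolerance = 1e-12)
  # non-normalized prior is normalized with a warning
  expect_warning(w2 <- derive_weights(pop, prior = c(2, 2)), "normaliz")
  expect_equal(w2$offsets, w$offsets)
})

test_that("posterior is a stable, shift-invariant softmax", {
  w <- structure(list(weights = matrix(c(0, log(3)), 2, 1),
                      offsets = c(0, 0), prior = c(0.5, 0.5),
                      stimulus_grid = c(-45, 45), provenance = "analytic",
                      max_residual = 0),
                 class = "decoder_weights")
  p <- posterior(w, matrix(1))
  expect_equal(as.numeric(p), c(0.25, 0.75), tolerance = 1e-12)
  expect_equal(rowSums(p), 1, tolerance = 1e-12)
  # equal logits: uniform
  w$weights <- matrix(c(1, 1), 2, 1)
  expect_equal(as.numeric(posterior(w, matrix(2))), c(0.5, 0.5))
  # adding a constant to every offset changes nothing
  w$offsets <- w$offsets + 37
  expect_equal(as.numeric(posterior(w, matrix(2))), c(0.5, 0.5))
  # extreme logits do not overflow
  w$weights <- matrix(c(0, 5000), 2, 1)
  expect_equal(rowSums(posterior(w, matrix(1))), 1)
  expect_error(posterior(w, c(1, 2, 3)))
})

test_that("MAP picks the argmax class with deterministic tie-breaking", {
  grid <- c(-45, 0, 45)
  expect_equal(map_estimate(c(0.1, 0.8, 0.1), grid), 0)
  expect_equal(map_estimate(c(0.5, 0.5), c(-45, 45)), -45)
  # noiseless self-consistency: R = f(theta_k) decodes to theta_k for all k
  pop <- small_population(30, "heterogeneous", 0.25, seed = 21)
  w <- derive_weights(pop)
  est <- map_estimate(posterior(w, pop$mean_response), w$stimulus_grid)
  expect_equal(est, pop$stimulus_grid)
})

test_that("per-stimulus circular MSE aggregates wrapped errors", {
  ce <- circular_error(c(0, 0, 45, -80), c(0, 22.5, 45, 80))
  expect_equal(ce$mse[ce$stimulus_deg == 45], 0)
  expect_equal(ce$mse[ce$stimulus_deg == 80], (20 * pi / 180)^2,
               tolerance = 1e-12)
  expect_true(all(ce$mse >= 0 & ce$mse <= (pi / 2)^2 + 1e-12))
  expect_equal(attr(ce, "performance"), 1 / attr(ce, "overall"))
})

test_that("weight smoothing is progressive and preserves constants", {
  pop <- small_population(200, "heterogeneous", 0.25, seed = 31)
  w <- derive_weights(pop)
  expect_identical(smooth_weights(w, pop, 0, 0), w)
  o <- order(pop$neurons$phi_deg)
  hf <- function(ww) var(diff(ww$weights[5, o]))
  h <- vapply(list(c(0.1, 1), c(0.2, 2), c(1, 10)), function(rho) {
    hf(smooth_weights(w, pop, rho[1], rho[2]))
  }, numeric(1))
  # high-frequency content strictly decreases with stronger smoothing
  expect_true(all(diff(c(hf(w), h)) < 0))
  # a constant weight row passes through any row-normalized smoother
  wc <- w
  wc$weights <- matrix(1.7, nrow(w$weights), ncol(w$weights))
  ws <- smooth_weights(wc, pop, 0.3, 5)
  expect_equal(ws$weights, wc$weights, tolerance = 1e-12)
  expect_error(smooth_weights(w, pop, 0.1, 0))
})

test_that("logistic regression recovers the analytic decoder", {
  pop <- small_population(6, "heterogeneous", 0.2, n_stimuli = 4, seed = 77)
  w_an <- derive_weights(pop)
  train <- simulate_responses(pop, 10000, seed = 78)
  w_lg <- fit_weights_logistic(train)
  expect_equal(w_lg$provenance, "logistic")
  # same data, same fit (determinism)
  w_lg2 <- fit_weights_logistic(train)
  expect_identical(w_lg$weights, w_lg2$weights)
  # weight rows agree up to the per-neuron offset degeneracy of the softmax
  ctr <- function(W) sweep(W, 2, colMeans(W))
  for (k in 1:4) {
    expect_gt(cor(ctr(w_lg$weights)[k, ], ctr(w_an$weights)[k, ]), 0.9)
  }
  # MAP labels agree on held-out trials
  held <- simulate_responses(pop, 500, seed = 79)
  X <- apply(held$responses, 3, identity)
  est_lg <- map_estimate(posterior(w_lg, X), pop$stimulus_grid)
  est_an <- map_estimate(posterior(w_an, X), pop$stimulus_grid)
  expect_gt(mean(est_lg == est_an), 0.95)
  # labels independent of responses: ridge shrinks weights to near zero
  X_tr <- apply(train$responses, 3, identity)
  set.seed(80)
  w_null <- fit_weights_logistic(X_tr, sample(rep(1:4, length.out = nrow(X_tr))),
                                 lambda = 1)
  expect_lt(max(abs(w_null$weights)), 0.02 * max(abs(w_lg$weights)))
})

test_that("accuracy sweep returns the full grid and finite errors", {
  sw <- accuracy_sweep(kinds = "homogeneous", n_grid = c(4, 16),
                       c_o_grid = 0, n_seeds = 2, n_stimuli = 24,
                       trials_per_stimulus = 10, seed = 5)
  expect_equal(nrow(sw), 4)
  expect_true(all(is.finite(sw$mse)))
  expect_true(all(sw$mse >= 0 & sw$mse <= (pi / 2)^2))
  # performance improves with population size in every replicate
  agg <- tapply(sw$mse, sw$n_neurons, mean)
  expect_lt(agg[["16"]], agg[["4"]])
})
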