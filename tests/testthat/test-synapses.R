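test_that("positive weights become sampling frequencies", {
  expect_equal(weights_to_frequency(c(2, -1, 2)), c(0.5, 0, 0.5))
  expect_equal(weights_to_frequency(rep(3, 5)), rep(0.2, 5))
  expect_equal(weights_to_frequency(c(5, 0, 0)), c(1, 0, 0))
  expect_error(weights_to_frequency(c(-1, 0, -2)), "positive")
  expect_equal(sum(weights_to_frequency(rnorm(100) + 0.2)), 1)
})

test_that("synapse draws follow the sampling distribution", {
  pop <- small_population(8, "homogeneous", 0, seed = 2)
  # degenerate distribution: every synapse shares the single source
  probs <- c(1, rep(0, 7))
  syn <- sample_synapses(pop, probs, n_synapses = 20, replace = TRUE, seed = 3)
  expect_true(all(syn$source_indices == 1))
  expect_true(all(apply(syn$tuning, 1, identical, syn$tuning[1, ])))
  # without replacement a single positive source cannot give 20 synapses
  expect_error(sample_synapses(pop, probs, n_synapses = 20, replace = FALSE),
               "distinct")
  # multinomial law: counts proportional to probs (chi-square GOF)
  probs <- weights_to_frequency(c(4, 3, 2, 1, 0, -1, 0.5, 0.5))
  syn <- sample_synapses(pop, probs, n_synapses = 1e5, replace = TRUE, seed = 4)
  counts <- tabulate(syn$source_indices, nbins = 8)
  keep <- probs > 0
  gof <- chisq.test(counts[keep], p = probs[keep])
  expect_gt(gof$p.value, 0.01)
})

test_that("sampled preferences track the positive-weight profile over phi", {
  pop <- small_population(400, "homogeneous", 0.2, seed = 11)
  w <- derive_weights(pop)
  k <- 5  # decoder neuron at 0 degrees
  probs <- weights_to_frequency(w$weights[k, ])
  syn <- sample_synapses(pop, probs, n_synapses = 2e4, replace = TRUE, seed = 12)
  prefs <- pop$neurons$phi_deg[syn$source_indices]
  # histogram over coarse bins converges to the binned probability mass
  bins <- seq(-90, 90, by = 22.5)
  emp <- table(cut(prefs, bins)) / length(prefs)
  thr <- tapply(probs, cut(pop$neurons$phi_deg, bins), sum)
  expect_equal(as.numeric(emp), as.numeric(thr), tolerance = 0.02)
  # modal sampled preference sits at the decoder neuron's orientation
  centered_bins <- seq(-101.25, 101.25, by = 22.5)
  mode_bin <- names(which.max(table(cut(prefs, centered_bins))))
  expect_equal(mode_bin, "(-11.2,11.2]")
})

test_that("synaptic trial noise has the advertised structure", {
  pop <- small_population(30, "heterogeneous", 0.2, seed = 13)
  syn <- sample_synapses(pop, rep(1 / 30, 30), n_synapses = 5, seed = 14)
  # near-noiseless limit: shrink the shared component, use shared-only model
  pop0 <- pop
  pop0$covariance <- pop$covariance * 1e-20
  s0 <- simulate_synaptic_trials(syn, pop0, n_trials = 4, seed = 15,
                                 noise_model = "shared")
  for (s in 1:5) {
    expect_equal(colMeans(s0$trial_responses[, , s]), syn$tuning[s, ],
                 tolerance = 1e-8)
  }
  # default model: trial sd at a stimulus ~ sqrt(Q_ii + rate there)
  sm <- simulate_synaptic_trials(syn, pop, n_trials = 4000, seed = 16)
  qii <- diag(pop$covariance)[syn$source_indices]
  for (s in c(1, 3)) {
    sd_obs <- apply(sm$trial_responses[, , s], 2, sd)
    sd_exp <- sqrt(qii[s] + pmax(syn$tuning[s, ], 1e-3))
    expect_equal(sd_obs, sd_exp, tolerance = 0.08)
  }
  # determinism: same seed reproduces the trial tensor bit for bit
  a <- simulate_synaptic_trials(syn, pop, n_trials = 6, seed = 17)
  b <- simulate_synaptic_trials(syn, pop, n_trials = 6, seed = 17)
  expect_identical(a$trial_responses, b$trial_responses)
  expect_error(simulate_synaptic_trials(syn, pop, n_trials = 1))
})

test_that("decoder output tuning rides along with simulated trials", {
  pop <- small_population(50, "homogeneous", 0.2, seed = 18)
  w <- derive_weights(pop)
  probs <- weights_to_frequency(w$weights[3, ])
  syn <- sample_synapses(pop, probs, n_synapses = 10, seed = 19)
  syn <- simulate_synaptic_trials(syn, pop, n_trials = 5, seed = 20,
                                  weights = w, class_index = 3)
  expect_equal(length(syn$decoder_output), 8)
  expect_equal(syn$decoder_output,
               decoder_output_tuning(w, pop)[, 3], tolerance = 1e-12)
  # the readout neuron responds maximally to its own stimulus class
  expect_equal(which.max(syn$decoder_output), 3)
})
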