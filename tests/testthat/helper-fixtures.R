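# Shared fixtures. The synapse-comparison simulations are expensive, so they
# are computed once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_population <- function(n = 40, kind = "homogeneous", c_o = 0.25,
                             n_stimuli = 8, seed = 42) {
  make_population(population_spec(n, kind, c_o, n_stimuli = n_stimuli,
                                  seed = seed))
}

# hand-built population with a chosen covariance, for oracle tests
manual_population <- function(mean_response, covariance, grid) {
  n <- ncol(mean_response)
  structure(
    list(neurons = data.frame(alpha = rep(0, n), beta = rep(1, n),
                              kappa = rep(1, n),
                              phi_deg = seq(-90, 90, length.out = n + 1)[1:n],
                              mean_rate = colMeans(mean_response)),
         stimulus_grid = grid, mean_response = mean_response,
         correlation = diag(n), covariance = covariance, jitter = 0,
         spec = NULL),
    class = "input_population")
}

# study-condition simulations at reduced replication (shared by the
# acceptance criteria and the distribution-level property tests)
comparison_runs <- function(kind) {
  cached(paste0("cmp_", kind), run_synapse_comparison(
    kind, n_runs = 60, n_neurons = 1000, max_correlation = 0.20,
    n_synapses = 100, n_trials = 10, n_stimuli = 8,
    seed = if (kind == "homogeneous") 101 else 202))
}
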