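#' Convert a decoder weight row into synaptic sampling probabilities
#'
#' Excitatory synapses cannot carry negative weights, so only the positive
#' part of a weight vector maps onto synapses: negative and zero weights get
#' probability zero and the positive weights are normalized to sum to one.
#' Greater weight amplitude then equates to a greater frequency of occurrence
#' in the sampled synaptic population.
#'
#' @param weight_row Numeric weight vector over the input population.
#' @return Probability vector of the same length (sums to 1).
#' @export
#' @examples
#' weights_to_frequency(c(2, -1, 2))  # 0.5, 0, 0.5
weights_to_frequency <- function(weight_row) {
  stopifnot(is.numeric(weight_row), length(weight_row) >= 1,
            all(is.finite(weight_row)))
  pos <- pmax(weight_row, 0)
  if (sum(pos) <= 0) {
    stop("weights_to_frequency(): no positive weights; ",
         "cannot form an excitatory synaptic population")
  }
  pos / sum(pos)
}

#' Sample a synaptic input population from a decoder neuron's weights
#'
#' Draws `n_synapses` source neurons from the input population with
#' probability proportional to the positive decoder weights, and evaluates
#' each source's tuning curve on the (typically coarse, 22.5-degree)
#' experimental stimulus grid. By default inputs are distinct neurons
#' (`replace = FALSE`); sampling with replacement treats duplicated draws as
#' one synapse of larger weight and is available for convergence checks.
#'
#' @param pop The input population the weights were derived from.
#' @param probs Sampling probabilities over neurons, e.g. from
#'   [weights_to_frequency()].
#' @param n_synapses Number of synapses (default 100, the typical count of
#'   visually responsive spines recovered per imaged cell).
#' @param stimulus_grid Orientation grid the synaptic tuning is sampled on
#'   (default the 8-point, 22.5-degree grid used in the imaging experiments).
#' @param replace Sample with replacement? Default FALSE.
#' @param seed Integer seed.
#' @return Object of class `"synaptic_population"`: `source_indices`,
#'   `tuning` (n_syn x K_stim noiseless mean responses), `stimulus_grid`,
#'   `probs`, `seed`; `trial_responses` and `decoder_output` are filled in by
#'   [simulate_synaptic_trials()].
#' @export
sample_synapses <- function(pop, probs, n_synapses = 100,
                            stimulus_grid = popdecode::stimulus_grid(8),
                            replace = FALSE, seed = 1L) {
  stopifnot(inherits(pop, "input_population"),
            length(probs) == nrow(pop$neurons),
            all(probs >= 0), abs(sum(probs) - 1) < 1e-8,
            n_synapses >= 1)
  if (!replace && sum(probs > 0) < n_synapses) {
    stop(sprintf("only %d inputs have positive probability; cannot draw %d distinct synapses",
                 sum(probs > 0), n_synapses))
  }
  set.seed(seed)
  src <- sample(seq_along(probs), n_synapses, replace = replace, prob = probs)
  nn <- pop$neurons
  tun <- t(tuning_matrix(stimulus_grid, nn$alpha[src], nn$beta[src],
                         nn$kappa[src], nn$phi_deg[src]))  # n_syn x K
  structure(
    list(source_indices = src, tuning = tun, stimulus_grid = stimulus_grid,
         probs = probs, replace = replace, seed = as.integer(seed),
         trial_responses = NULL, decoder_output = NULL),
    class = "synaptic_population"
  )
}

#' @export
print.synaptic_population <- function(x, ...) {
  cat(sprintf("synaptic_population: %d synapses on %d-point grid%s\n",
              nrow(x$tuning), length(x$stimulus_grid),
              if (is.null(x$trial_responses)) "" else
                sprintf(", %d trials simulated", dim(x$trial_responses)[1])))
  invisible(x)
}

#' Simulate calcium-trial-like responses of a synaptic population
#'
#' Adds trial-to-trial noise to every synapse's tuning curve. The default
#' noise model combines the two variance components of the population model:
#' the shared, stimulus-independent variance each source neuron has under the
#' decoder's covariance (Q_ii, its stimulus-averaged mean rate) plus a private
#' Poisson-like component whose variance equals the mean response at that
#' stimulus. Alternatives: `"rate"` (private Poisson-like only) and
#' `"shared"` (stimulus-independent only). Noise is drawn independently
#' across synapses unless `correlated = TRUE`, in which case the shared
#' component uses the corresponding rows of Q.
#'
#' Also computes the decoder neuron's output tuning (its softmax response to
#' the noiseless population mean at each grid stimulus) when `weights` and
#' `class_index` are supplied.
#'
#' @param syn A [sample_synapses()] result.
#' @param pop The input population.
#' @param n_trials Trials per stimulus (>= 2; default 10, matching the 8-10
#'   trials of the imaging experiments).
#' @param seed Integer seed.
#' @param noise_model One of `"shared_plus_rate"`, `"rate"`, `"shared"`.
#' @param correlated Draw the shared noise component jointly across synapses
#'   from Q? Default FALSE (independent).
#' @param weights,class_index Optionally, the decoder and the class whose
#'   weights generated this synaptic population; fills `decoder_output`.
#' @param rate_floor Variance floor.
#' @return The synaptic population with `trial_responses`
#'   (n_trials x K_stim x n_syn) and optionally `decoder_output` filled in.
#' @export
simulate_synaptic_trials <- function(syn, pop, n_trials = 10, seed = 1L,
                                     noise_model = c("shared_plus_rate", "rate", "shared"),
                                     correlated = FALSE,
                                     weights = NULL, class_index = NULL,
                                     rate_floor = 1e-3) {
  stopifnot(inherits(syn, "synaptic_population"),
            inherits(pop, "input_population"))
  noise_model <- match.arg(noise_model)
  if (n_trials < 2) stop("'n_trials' must be >= 2")
  n_trials <- as.integer(n_trials)
  K <- length(syn$stimulus_grid)
  ns <- nrow(syn$tuning)
  src <- syn$source_indices
  qii <- diag(pop$covariance)[src]
  rate_var <- pmax(t(syn$tuning), rate_floor)           # K x n_syn
  shared_var <- matrix(qii, K, ns, byrow = TRUE)        # K x n_syn
  priv_var <- switch(noise_model,
    shared_plus_rate = rate_var,
    rate = rate_var,
    shared = matrix(0, K, ns))
  use_shared <- noise_model %in% c("shared_plus_rate", "shared")
  set.seed(seed)
  arr <- array(NA_real_, dim = c(n_trials, K, ns))
  mean_k <- t(syn$tuning)                                # K x n_syn
  if (use_shared && correlated) {
    chs <- chol(pop$covariance[src, src, drop = FALSE])
  }
  for (tt in seq_len(n_trials)) {
    shared <- if (!use_shared) {
      matrix(0, K, ns)
    } else if (correlated) {
      # shared draws correlated across synapses via the Q submatrix
      matrix(stats::rnorm(K * ns), K, ns) %*% chs
    } else {
      matrix(stats::rnorm(K * ns), K, ns) * sqrt(shared_var)
    }
    private <- if (noise_model == "shared") {
      matrix(0, K, ns)
    } else {
      matrix(stats::rnorm(K * ns), K, ns) * sqrt(priv_var)
    }
    arr[tt, , ] <- mean_k + shared + private
  }
  syn$trial_responses <- arr
  syn$n_trials <- n_trials
  syn$noise_model <- noise_model
  syn$trial_seed <- as.integer(seed)
  if (!is.null(weights)) {
    stopifnot(inherits(weights, "decoder_weights"))
    out <- posterior(weights, pop$mean_response)
    if (is.null(class_index)) {
      stop("'class_index' must accompany 'weights'")
    }
    # readout tuning evaluated on the synaptic stimulus grid: the decoder grid
    # must contain those stimuli
    idx <- match(round(syn$stimulus_grid, 9), round(weights$stimulus_grid, 9))
    if (any(is.na(idx))) {
      stop("synaptic stimulus grid is not a subset of the decoder grid")
    }
    syn$decoder_output <- out[idx, class_index]
  }
  syn
}
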