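#' Analytic maximum-likelihood decoder weights
#'
#' For Gaussian population responses with stimulus-independent covariance Q,
#' the posterior over stimulus classes is a softmax of linear functions of the
#' response vector, with weights and offsets available in closed form:
#' \deqn{w_k = Q^{-1} f(\theta_k), \qquad
#'       \beta_k = -\tfrac12 f(\theta_k)^\top Q^{-1} f(\theta_k) + \log p(\theta_k).}
#' Weights are obtained by a Cholesky-backed linear solve (never an explicit
#' inverse). When Q is diagonal the weights reduce to the per-neuron
#' signal-to-noise ratio, mean over variance.
#'
#' @param pop An [make_population()] result (Q must be positive definite).
#' @param prior Prior probabilities over the K stimulus classes; defaults to
#'   uniform. Normalized with a warning if it does not sum to one.
#' @return Object of class `"decoder_weights"`: `weights` (K x N, one row per
#'   stimulus class), `offsets` (K), `prior` (K), `stimulus_grid`,
#'   `provenance = "analytic"`, and `max_residual`, the largest relative
#'   residual of the solves.
#' @export
#' @examples
#' pop <- make_population(population_spec(40, "homogeneous", 0.25, seed = 7))
#' w <- derive_weights(pop)
#' max(abs(pop$covariance %*% t(w$weights) - t(pop$mean_response)))
derive_weights <- function(pop, prior = NULL) {
  stopifnot(inherits(pop, "input_population"))
  K <- length(pop$stimulus_grid)
  if (is.null(prior)) prior <- rep(1 / K, K)
  stopifnot(length(prior) == K, all(prior > 0))
  if (abs(sum(prior) - 1) > 1e-12) {
    warning("prior did not sum to 1; normalizing")
    prior <- prior / sum(prior)
  }
  ch <- tryCatch(chol(pop$covariance), error = function(e) {
    stop("derive_weights(): covariance is not positive definite (",
         conditionMessage(e), ")")
  })
  fT <- t(pop$mean_response)                       # N x K
  W <- backsolve(ch, forwardsolve(t(ch), fT))      # N x K, solves Q w = f
  resid <- pop$covariance %*% W - fT
  rel <- max(abs(resid)) / max(abs(fT))
  if (rel > 1e-8) {
    warning(sprintf("weight solve relative residual %.3g exceeds 1e-8", rel))
  }
  offsets <- -0.5 * colSums(fT * W) + log(prior)
  structure(
    list(weights = t(W), offsets = as.numeric(offsets), prior = prior,
         stimulus_grid = pop$stimulus_grid, provenance = "analytic",
         max_residual = rel),
    class = "decoder_weights"
  )
}

#' @export
print.decoder_weights <- function(x, ...) {
  cat(sprintf("decoder_weights: %d classes x %d neurons (%s)\n",
              nrow(x$weights), ncol(x$weights), x$provenance))
  invisible(x)
}

# numerically stable softmax over rows
softmax_rows <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

#' Posterior probabilities of the decoder
#'
#' Evaluates \eqn{p(\theta_k | R) \propto \exp(R^\top w_k + \beta_k)} for one
#' response vector or a batch of rows, with a numerically stable softmax.
#'
#' @param weights A [derive_weights()] (or smoothed/logistic) object.
#' @param R Response vector of length N, or a trials x N matrix.
#' @return Matrix trials x K of posterior probabilities; rows sum to one.
#' @export
posterior <- function(weights, R) {
  stopifnot(inherits(weights, "decoder_weights"))
  if (is.vector(R)) R <- matrix(R, nrow = 1)
  if (ncol(R) != ncol(weights$weights)) {
    stop(sprintf("response length %d does not match %d neurons",
                 ncol(R), ncol(weights$weights)))
  }
  L <- R %*% t(weights$weights) +
    matrix(weights$offsets, nrow(R), length(weights$offsets), byrow = TRUE)
  softmax_rows(L)
}

#' Maximum a posteriori orientation estimate
#'
#' @param post Posterior matrix (trials x K), e.g. from [posterior()].
#' @param grid Stimulus grid of length K (defaults to the attribute carried by
#'   a `posterior()` call is not kept, so pass the decoder's grid).
#' @return Orientation (degrees) of the argmax class per trial; exact ties go
#'   to the lowest class index.
#' @export
map_estimate <- function(post, grid) {
  if (is.vector(post)) post <- matrix(post, nrow = 1)
  stopifnot(ncol(post) == length(grid))
  grid[max.col(post, ties.method = "first")]
}

#' Per-stimulus circular mean squared error
#'
#' Aggregates squared wrapped orientation errors (see
#' [orientation_sq_error()]) by true stimulus. The attribute `overall` holds
#' the grand mean and `performance` its inverse, the decoder-performance
#' measure used in the accuracy sweeps.
#'
#' @param estimates,truths Orientations in degrees, equal length.
#' @return data.frame with columns `stimulus_deg`, `n`, `mse`; attributes
#'   `overall` (mean over trials) and `performance` (1 / overall).
#' @export
circular_error <- function(estimates, truths) {
  stopifnot(length(estimates) == length(truths))
  err <- orientation_sq_error(estimates, truths)
  agg <- stats::aggregate(err, by = list(stimulus_deg = truths), FUN = mean)
  cnt <- stats::aggregate(err, by = list(stimulus_deg = truths), FUN = length)
  out <- data.frame(stimulus_deg = agg$stimulus_deg, n = cnt$x, mse = agg$x)
  attr(out, "overall") <- mean(err)
  attr(out, "performance") <- 1 / mean(err)
  out
}

#' Smooth decoder weights over orientation preference
#'
#' Applies a smoothness penalty to each weight row: neurons are coupled by the
#' kernel \eqn{S_{ij} = e^{-(\rho_1 + \delta(\phi_i, \phi_j)/\rho_2)}} with
#' \eqn{\delta} the circular orientation-preference difference in degrees, and
#' each weight row is replaced by the row-normalized kernel average. The
#' kernel's amplitude \eqn{e^{-\rho_1}} cancels under row normalization (so
#' the smoother preserves constant weight vectors and MAP decoding is
#' invariant to it); \eqn{\rho_2} sets the functional range of smoothing in
#' degrees of orientation preference.
#' `(0, 0)` is the no-smoothing sentinel and returns the weights unchanged.
#' Offsets are recomputed as \eqn{-\tfrac12 f(\theta_k)^\top \tilde w_k + \log p(\theta_k)}
#' so the readout stays calibrated for the smoothed weights.
#'
#' @param weights A `"decoder_weights"` object.
#' @param pop The population the weights were derived from (provides the
#'   preferences and mean responses).
#' @param rho1 Smoothing amplitude (>= 0).
#' @param rho2 Smoothing range in degrees (> 0 unless both are 0).
#' @return A `"decoder_weights"` object with provenance `"smoothed"`.
#' @export
smooth_weights <- function(weights, pop, rho1, rho2) {
  stopifnot(inherits(weights, "decoder_weights"),
            inherits(pop, "input_population"),
            length(rho1) == 1, length(rho2) == 1, rho1 >= 0)
  if (rho1 == 0 && rho2 == 0) return(weights)
  if (rho2 <= 0) stop("'rho2' must be > 0 (or use the (0,0) sentinel)")
  phi <- pop$neurons$phi_deg
  D <- outer(phi, phi, orientation_diff)
  S <- exp(-(rho1 + D / rho2))
  M <- S / rowSums(S)
  W <- weights$weights %*% t(M)
  offsets <- -0.5 * rowSums(W * pop$mean_response) + log(weights$prior)
  structure(
    list(weights = W, offsets = as.numeric(offsets), prior = weights$prior,
         stimulus_grid = weights$stimulus_grid,
         provenance = sprintf("smoothed(%g,%g)", rho1, rho2),
         max_residual = NA_real_),
    class = "decoder_weights"
  )
}

#' Numerical decoder weights via multinomial logistic regression
#'
#' The analytic weights exist because the noise is Gaussian with equal
#' covariance; more generally the same softmax readout can be estimated
#' numerically. This fits a ridge-regularized multinomial logistic regression
#' (a light penalty keeps the solution identified) and packages the
#' coefficients as decoder weights.
#'
#' @param responses A `"response_set"` from [simulate_responses()], or a
#'   (trials x N) matrix.
#' @param labels Class labels: for a `"response_set"`, omit (stimulus indices
#'   are implied); for a matrix, an integer/factor vector of length nrow.
#' @param lambda Ridge penalty (default 1e-4).
#' @return A `"decoder_weights"` object with provenance `"logistic"`. The
#'   class grid is taken from the response set (or `sort(unique(labels))`
#'   interpreted as orientations when a matrix is given).
#' @export
fit_weights_logistic <- function(responses, labels = NULL, lambda = 1e-4) {
  if (inherits(responses, "response_set")) {
    d <- dim(responses$responses)
    X <- apply(responses$responses, 3, identity)  # (trials*K) x N, trial fastest
    y <- rep(seq_len(d[2]), each = d[1])
    grid <- responses$stimulus_grid
  } else {
    X <- as.matrix(responses)
    if (is.null(labels)) stop("'labels' required when 'responses' is a matrix")
    stopifnot(length(labels) == nrow(X))
    f <- factor(labels)
    y <- as.integer(f)
    grid <- suppressWarnings(as.numeric(levels(f)))
    if (any(is.na(grid))) grid <- seq_along(levels(f))
  }
  K <- length(unique(y))
  if (K < 2) stop("need at least 2 classes")
  if (nrow(X) < K) stop("need at least as many trials as classes")
  fit <- glmnet::glmnet(X, factor(y), family = "multinomial", alpha = 0,
                        lambda = lambda, standardize = FALSE,
                        thresh = 1e-10, maxit = 1e6)
  cf <- stats::coef(fit, s = lambda)
  W <- t(vapply(cf, function(b) as.numeric(b)[-1], numeric(ncol(X))))
  offsets <- vapply(cf, function(b) as.numeric(b)[1], numeric(1))
  structure(
    list(weights = W, offsets = as.numeric(offsets),
         prior = as.numeric(table(y)) / length(y),
         stimulus_grid = grid, provenance = "logistic",
         max_residual = NA_real_),
    class = "decoder_weights"
  )
}

#' Decoder output tuning curves
#'
#' The "somatic" tuning of each readout neuron: the noiseless mean population
#' response to every stimulus pushed through the softmax readout. Column k is
#' the tuning curve of the decoder neuron for class k across the stimuli in
#' rows.
#'
#' @param weights A `"decoder_weights"` object.
#' @param pop The input population.
#' @return K_stim x K_class matrix of readout responses.
#' @export
decoder_output_tuning <- function(weights, pop) {
  stopifnot(inherits(weights, "decoder_weights"),
            inherits(pop, "input_population"))
  posterior(weights, pop$mean_response)
}

#' Decoding-accuracy sweep over population size, correlation and smoothing
#'
#' For every combination of population kind, size N, maximum correlation c_o
#' and smoothing parameters, builds a fresh population, derives (and
#' optionally smooths) the analytic weights, evaluates the MAP estimator on
#' freshly seeded held-out trials, and reports the circular MSE and its
#' inverse ("performance"). Each grid cell is replicated `n_seeds` times with
#' independent populations and evaluation sets.
#'
#' The default stimulus grid is fine (`n_stimuli = 120`, 1.5-degree spacing)
#' so that the MSE tracks estimation precision rather than collapsing to zero
#' once every class is separable; see the package vignette.
#'
#' @param kinds Character vector of population kinds.
#' @param n_grid Integer vector of population sizes.
#' @param c_o_grid Numeric vector of maximum correlations.
#' @param smoothing_grid List of `c(rho1, rho2)` pairs; `c(0, 0)` means no
#'   smoothing.
#' @param n_seeds Replicates per cell.
#' @param n_stimuli Stimulus classes for decoding.
#' @param trials_per_stimulus Held-out evaluation trials per class.
#' @param seed Master seed; all population and evaluation seeds derive from it.
#' @return data.frame with one row per (cell, replicate):
#'   kind, n_neurons, c_o, rho1, rho2, replicate, mse, performance.
#' @export
accuracy_sweep <- function(kinds = c("homogeneous", "heterogeneous"),
                           n_grid = 2^(2:9),
                           c_o_grid = c(0, 0.25, 0.5),
                           smoothing_grid = list(c(0, 0)),
                           n_seeds = 5,
                           n_stimuli = 120,
                           trials_per_stimulus = 20,
                           seed = 1L) {
  stopifnot(length(n_grid) >= 1, length(c_o_grid) >= 1,
            length(smoothing_grid) >= 1, n_seeds >= 1)
  cells <- expand.grid(kind = kinds, n_neurons = n_grid, c_o = c_o_grid,
                       smooth = seq_along(smoothing_grid),
                       replicate = seq_len(n_seeds),
                       stringsAsFactors = FALSE)
  seeds <- derive_seeds(seed, 2 * nrow(cells))
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    rho <- smoothing_grid[[cell$smooth]]
    res <- tryCatch({
      spec <- population_spec(cell$n_neurons, cell$kind, cell$c_o,
                              n_stimuli = n_stimuli, seed = seeds[2 * i - 1])
      pop <- make_population(spec)
      w <- derive_weights(pop)
      if (!(rho[1] == 0 && rho[2] == 0)) w <- smooth_weights(w, pop, rho[1], rho[2])
      ev <- simulate_responses(pop, trials_per_stimulus, seed = seeds[2 * i])
      d <- dim(ev$responses)
      X <- apply(ev$responses, 3, identity)
      truths <- rep(pop$stimulus_grid, each = d[1])
      est <- map_estimate(posterior(w, X), w$stimulus_grid)
      mean(orientation_sq_error(est, truths))
    }, error = function(e) {
      message(sprintf("sweep cell %s/N=%d/c_o=%g failed: %s",
                      cell$kind, cell$n_neurons, cell$c_o, conditionMessage(e)))
      NA_real_
    })
    out[[i]] <- data.frame(kind = cell$kind, n_neurons = cell$n_neurons,
                           c_o = cell$c_o, rho1 = rho[1], rho2 = rho[2],
                           replicate = cell$replicate, mse = res,
                           performance = 1 / res)
  }
  do.call(rbind, out)
}
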