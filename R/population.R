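#' Specify an orientation-tuned input population
#'
#' Collects the parameters that define a simulated input population: its size,
#' whether tuning is homogeneous (shifted copies of one curve) or
#' heterogeneous (V1-like variability in baseline, amplitude and bandwidth),
#' the maximum pairwise noise correlation, the stimulus grid, and the sampling
#' distributions used in the heterogeneous case.
#'
#' Heterogeneous tuning bandwidths are drawn as half-widths \eqn{\gamma} (in
#' radians) from a lognormal distribution and converted to concentrations with
#' [bandwidth_to_kappa()]. Amplitudes are lognormal and baselines exponential;
#' these two distributions are not constrained by the physiology the bandwidth
#' distribution comes from, so they are configurable.
#'
#' @param n_neurons Population size N (>= 2).
#' @param kind `"homogeneous"` or `"heterogeneous"`.
#' @param max_correlation Maximum pairwise noise correlation `c_o` in [0, 1):
#'   the correlation of two identically tuned neurons. Correlations decay
#'   exponentially with orientation-preference difference (limited range).
#' @param n_stimuli Number of stimulus classes K on \code{[-90, 90)}.
#' @param homogeneous_params Named vector `c(alpha=, beta=, kappa=)` shared by
#'   all neurons when `kind = "homogeneous"`.
#' @param bandwidth_lognormal `c(meanlog=, sdlog=)` of the half-width
#'   distribution (half-widths in radians), heterogeneous case.
#' @param amplitude_lognormal `c(meanlog=, sdlog=)` of the amplitude (beta)
#'   distribution, heterogeneous case.
#' @param baseline_exp_mean Mean of the exponential baseline (alpha)
#'   distribution, heterogeneous case.
#' @param seed Integer seed used by [make_population()].
#' @return An object of class `"population_spec"`.
#' @export
#' @examples
#' population_spec(100, "homogeneous", max_correlation = 0.25)
population_spec <- function(n_neurons,
                            kind = c("homogeneous", "heterogeneous"),
                            max_correlation = 0,
                            n_stimuli = 8,
                            homogeneous_params = c(alpha = 0, beta = 5, kappa = 4),
                            bandwidth_lognormal = c(meanlog = -1, sdlog = 0.6),
                            amplitude_lognormal = c(meanlog = log(5), sdlog = 0.5),
                            baseline_exp_mean = 0.5,
                            seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(
    length(n_neurons) == 1, is.finite(n_neurons), n_neurons >= 2,
    length(max_correlation) == 1, max_correlation >= 0, max_correlation < 1,
    length(n_stimuli) == 1, n_stimuli >= 2,
    length(seed) == 1, is.finite(seed)
  )
  hp <- homogeneous_params
  if (!all(c("alpha", "beta", "kappa") %in% names(hp))) {
    stop("'homogeneous_params' needs named entries alpha, beta, kappa")
  }
  structure(
    list(
      n_neurons = as.integer(n_neurons),
      kind = kind,
      max_correlation = max_correlation,
      n_stimuli = as.integer(n_stimuli),
      stimulus_grid = stimulus_grid(n_stimuli),
      homogeneous_params = hp[c("alpha", "beta", "kappa")],
      bandwidth_lognormal = bandwidth_lognormal,
      amplitude_lognormal = amplitude_lognormal,
      baseline_exp_mean = baseline_exp_mean,
      seed = as.integer(seed)
    ),
    class = "population_spec"
  )
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("population_spec: %d %s neurons, c_o = %g, K = %d, seed = %d\n",
              x$n_neurons, x$kind, x$max_correlation, x$n_stimuli, x$seed))
  invisible(x)
}

#' Limited-range noise-correlation matrix
#'
#' Pairwise noise correlations that decay exponentially with the difference in
#' preferred orientation: \eqn{A_{ij} = c_o e^{-|\delta(\phi_i - \phi_j)|}}
#' with \eqn{\delta} the circular orientation difference in radians (in
#' \code{[0, pi/2]}), and \eqn{C = A + (1 - c_o) I} so the diagonal is exactly
#' one. Two identically tuned neurons are correlated at `c_o`.
#'
#' @param preferences Preferred orientations, degrees.
#' @param max_correlation `c_o` in [0, 1).
#' @return N x N correlation matrix.
#' @export
#' @examples
#' build_correlation_matrix(c(0, 0, 90), 0.25)
build_correlation_matrix <- function(preferences, max_correlation) {
  stopifnot(is.numeric(preferences), length(preferences) >= 1,
            length(max_correlation) == 1)
  if (max_correlation < 0 || max_correlation >= 1) {
    stop("'max_correlation' must be in [0, 1): at 1 the off-diagonal of two ",
         "co-tuned neurons would reach the diagonal")
  }
  n <- length(preferences)
  if (max_correlation == 0) return(diag(n))
  d <- outer(preferences, preferences,
             function(a, b) orientation_diff(a, b, unit = "rad"))
  max_correlation * exp(-d) + (1 - max_correlation) * diag(n)
}

#' Scale a correlation matrix to a Poisson-like covariance
#'
#' Produces the noise covariance \eqn{Q_{ij} = C_{ij}\sqrt{\mu_i \mu_j}} where
#' \eqn{\mu_i} is neuron i's stimulus-averaged mean rate. The variance of each
#' neuron then equals its mean rate (Poisson-like mean-variance scaling) while
#' the covariance stays stimulus-independent, as the analytic decoder
#' derivation requires.
#'
#' @param C Correlation matrix.
#' @param mean_rates Per-neuron stimulus-averaged mean rates (>= 0; values
#'   below `rate_floor` are floored with a warning to keep Q invertible).
#' @param rate_floor Minimum rate used in the scaling.
#' @return Covariance matrix Q.
#' @export
#' @examples
#' scale_to_covariance(diag(2), c(4, 9))  # diag(4, 9)
scale_to_covariance <- function(C, mean_rates, rate_floor = 1e-3) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C), length(mean_rates) == nrow(C))
  if (any(mean_rates < 0)) stop("'mean_rates' must be non-negative")
  if (any(mean_rates < rate_floor)) {
    warning(sprintf("%d mean rate(s) below %g floored for covariance scaling",
                    sum(mean_rates < rate_floor), rate_floor))
    mean_rates <- pmax(mean_rates, rate_floor)
  }
  s <- sqrt(mean_rates)
  C * tcrossprod(s)
}

#' Build an orientation-tuned input population
#'
#' Draws (or fixes) per-neuron tuning parameters according to the spec,
#' evaluates every tuning curve on the stimulus grid, and assembles the
#' limited-range correlation matrix and its rate-scaled covariance.
#'
#' Homogeneous populations share `homogeneous_params` and tile preferred
#' orientations uniformly over \code{[-90, 90)}. Heterogeneous populations
#' draw half-widths from the lognormal bandwidth distribution (radians,
#' converted through [bandwidth_to_kappa()]), amplitudes from a lognormal and
#' baselines from an exponential, with uniformly random preferences.
#'
#' @param spec A [population_spec()].
#' @return An object of class `"input_population"` with elements `neurons`
#'   (data.frame: alpha, beta, kappa, phi_deg, mean_rate),
#'   `stimulus_grid`, `mean_response` (K x N), `correlation` (N x N),
#'   `covariance` (N x N), `jitter` (diagonal jitter added if the Cholesky
#'   factorization initially failed, else 0) and `spec`.
#' @export
#' @examples
#' pop <- make_population(population_spec(40, "homogeneous", 0.25, seed = 7))
#' dim(pop$mean_response)
make_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_neurons
  set.seed(spec$seed)
  if (spec$kind == "homogeneous") {
    hp <- spec$homogeneous_params
    alpha <- rep(hp[["alpha"]], n)
    beta <- rep(hp[["beta"]], n)
    kappa <- rep(hp[["kappa"]], n)
    phi <- stimulus_grid(n)  # tile preferences uniformly
  } else {
    phi <- stats::runif(n, -90, 90)
    gamma_rad <- stats::rlnorm(n, spec$bandwidth_lognormal[["meanlog"]],
                               spec$bandwidth_lognormal[["sdlog"]])
    gamma_deg <- pmin(gamma_rad * 180 / pi, 89.99)
    kappa <- bandwidth_to_kappa(gamma_deg)
    beta <- stats::rlnorm(n, spec$amplitude_lognormal[["meanlog"]],
                          spec$amplitude_lognormal[["sdlog"]])
    alpha <- stats::rexp(n, rate = 1 / spec$baseline_exp_mean)
  }
  fm <- tuning_matrix(spec$stimulus_grid, alpha, beta, kappa, phi)
  mu <- colMeans(fm)
  C <- build_correlation_matrix(phi, spec$max_correlation)
  Q <- suppressWarnings(scale_to_covariance(C, mu))
  jitter <- 0
  ok <- tryCatch({ chol(Q); TRUE }, error = function(e) FALSE)
  if (!ok) {
    jitter <- 1e-8 * sum(diag(Q)) / n
    Q <- Q + diag(jitter, n)
    message(sprintf("make_population(): covariance not PD, added diagonal jitter %g", jitter))
  }
  structure(
    list(
      neurons = data.frame(alpha = alpha, beta = beta, kappa = kappa,
                           phi_deg = phi, mean_rate = mu),
      stimulus_grid = spec$stimulus_grid,
      mean_response = fm,
      correlation = C,
      covariance = Q,
      jitter = jitter,
      spec = spec
    ),
    class = "input_population"
  )
}

#' @export
print.input_population <- function(x, ...) {
  cat(sprintf("input_population: %d %s neurons, K = %d stimuli, c_o = %g\n",
              nrow(x$neurons), x$spec$kind, length(x$stimulus_grid),
              x$spec$max_correlation))
  invisible(x)
}

#' Simulate trial responses of an input population
#'
#' Draws `n_trials` responses per stimulus as the mean tuning response plus
#' correlated Gaussian noise with covariance Q (equal across stimuli). The
#' Gaussian is not rectified by default, matching the assumptions under which
#' the analytic decoder is optimal.
#'
#' @param pop An [make_population()] result.
#' @param n_trials Trials per stimulus (>= 1).
#' @param seed Integer seed.
#' @param rectify If TRUE, responses are clipped at zero (off by default).
#' @return Object of class `"response_set"`: a list with `responses`
#'   (array `n_trials` x K x N), `stimulus_grid`, `rectified` and `seed`.
#' @export
simulate_responses <- function(pop, n_trials, seed = 1L, rectify = FALSE) {
  stopifnot(inherits(pop, "input_population"),
            length(n_trials) == 1, is.finite(n_trials))
  if (n_trials < 1) stop("'n_trials' must be >= 1")
  n_trials <- as.integer(n_trials)
  K <- length(pop$stimulus_grid)
  n <- nrow(pop$neurons)
  ch <- chol(pop$covariance)
  set.seed(seed)
  arr <- array(NA_real_, dim = c(n_trials, K, n))
  for (k in seq_len(K)) {
    noise <- matrix(stats::rnorm(n_trials * n), n_trials, n) %*% ch
    arr[, k, ] <- noise + matrix(pop$mean_response[k, ], n_trials, n, byrow = TRUE)
  }
  if (rectify) arr <- pmax(arr, 0)
  structure(
    list(responses = arr, stimulus_grid = pop$stimulus_grid,
         rectified = rectify, seed = as.integer(seed)),
    class = "response_set"
  )
}

#' @export
print.response_set <- function(x, ...) {
  d <- dim(x$responses)
  cat(sprintf("response_set: %d trials x %d stimuli x %d neurons (seed %d)\n",
              d[1], d[2], d[3], x$seed))
  invisible(x)
}
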