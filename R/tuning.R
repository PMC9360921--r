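#' Orientation tuning curve
#'
#' Mean response of an orientation-tuned neuron,
#' \deqn{f(\theta) = \alpha + \beta \exp\{\kappa [\cos(2(\theta - \phi)) - 1]\},}
#' a circular-Gaussian-like curve that peaks at \eqn{\alpha + \beta} for
#' \eqn{\theta = \phi} and falls to \eqn{\alpha + \beta e^{-2\kappa}} at the
#' orthogonal orientation. The doubled angle makes the curve 180-degree
#' periodic, as orientation tuning must be.
#'
#' @param theta Stimulus orientation(s), degrees.
#' @param alpha Baseline response (rate units, >= 0).
#' @param beta Tuned response amplitude (>= 0).
#' @param kappa Concentration (dimensionless, > 0); larger is narrower.
#' @param phi Preferred orientation, degrees.
#' @return Mean response, recycled over the longest argument.
#' @seealso [bandwidth_to_kappa()] to convert a half-width to `kappa`.
#' @export
#' @examples
#' tuning_curve(0, alpha = 0, beta = 5, kappa = 4, phi = 0)   # peak: 5
#' tuning_curve(90, alpha = 0, beta = 5, kappa = 4, phi = 0)  # 5 * exp(-8)
tuning_curve <- function(theta, alpha, beta, kappa, phi) {
  if (!all(is.finite(theta), is.finite(alpha), is.finite(beta),
           is.finite(kappa), is.finite(phi))) {
    stop("tuning_curve(): all parameters must be finite")
  }
  if (any(kappa <= 0)) stop("tuning_curve(): 'kappa' must be > 0")
  if (any(alpha < 0) || any(beta < 0)) {
    stop("tuning_curve(): 'alpha' and 'beta' must be >= 0")
  }
  alpha + beta * exp(kappa * (cos(2 * (theta - phi) * pi / 180) - 1))
}

#' Convert tuning half-width to concentration
#'
#' Converts a tuning-curve half-width \eqn{\gamma} (degrees) into the
#' concentration \eqn{\kappa} of [tuning_curve()] via
#' \deqn{\kappa = \log 2 / (1 - \cos 2\gamma).}
#' The conversion is strictly decreasing in \eqn{\gamma}: narrow curves have
#' large \eqn{\kappa}. Very small half-widths overflow, so \eqn{\kappa} is
#' capped.
#'
#' @param gamma Half-width(s) in degrees, in (0, 90).
#' @param kappa_max Cap applied to the result (default 1000, i.e. half-widths
#'   narrower than about one degree saturate).
#' @return Concentration value(s).
#' @export
#' @examples
#' bandwidth_to_kappa(45)  # log(2)
bandwidth_to_kappa <- function(gamma, kappa_max = 1000) {
  stopifnot(is.numeric(gamma), length(kappa_max) == 1, kappa_max > 0)
  if (any(!is.finite(gamma)) || any(gamma <= 0) || any(gamma >= 90)) {
    stop("bandwidth_to_kappa(): 'gamma' must be in (0, 90) degrees")
  }
  pmin(log(2) / (1 - cos(2 * gamma * pi / 180)), kappa_max)
}

# K x N matrix of mean responses: row k = stimulus, column i = neuron
tuning_matrix <- function(theta, alpha, beta, kappa, phi) {
  n <- length(phi)
  vapply(seq_len(n), function(i) {
    tuning_curve(theta, alpha[i], beta[i], kappa[i], phi[i])
  }, numeric(length(theta)))
}
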