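#' Input-output tuning correlation
#'
#' Pearson correlation between an input's and the output's trial-averaged
#' tuning curves across orientations - the core statistic for comparing
#' synaptic populations (real or simulated) with their soma/readout.
#'
#' @param input_curve,output_curve Equal-length (>= 3) mean-response curves.
#' @return Pearson r, or `NA_real_` if either curve has zero variance (such
#'   inputs are excluded from distributions downstream).
#' @export
#' @examples
#' tuning_correlation(c(1, 2, 3, 4), c(2, 4, 5, 9))
tuning_correlation <- function(input_curve, output_curve) {
  stopifnot(length(input_curve) == length(output_curve),
            length(input_curve) >= 3)
  if (stats::sd(input_curve) == 0 || stats::sd(output_curve) == 0) {
    return(NA_real_)
  }
  stats::cor(input_curve, output_curve)
}

#' Tuning-correlation distribution of an input population
#'
#' Applies [tuning_correlation()] to every input against one output curve and
#' aggregates: the pooled per-input r values and their mean (the "per-cell
#' mean" when the inputs belong to one cell). Inputs with zero-variance curves
#' are excluded and counted.
#'
#' @param input_curves Matrix with one row per input (n x K), e.g.
#'   trial-averaged synapse or spine tuning curves.
#' @param output_curve Length-K output (soma or readout) tuning curve.
#' @return List: `r` (length n, NA for excluded), `mean_r`, `n_excluded`.
#' @export
correlation_distribution <- function(input_curves, output_curve) {
  stopifnot(is.matrix(input_curves), ncol(input_curves) == length(output_curve),
            nrow(input_curves) >= 1)
  r <- unname(apply(input_curves, 1, tuning_correlation,
                    output_curve = output_curve))
  list(r = r, mean_r = mean(r, na.rm = TRUE), n_excluded = sum(is.na(r)))
}

#' Histogram of correlation values as a probability vector
#'
#' Bins r values on \code{[-1, 1]} with the given bin width and an additive
#' pseudocount per bin (so downstream KL divergences are finite), then
#' normalizes to probabilities.
#'
#' @param r Correlation values (NAs dropped).
#' @param bin_width Bin width (default 0.05; 40 bins).
#' @param pseudocount Count added to every bin before normalization.
#' @return Probability vector with one entry per bin (attribute `"breaks"`).
#' @export
correlation_histogram <- function(r, bin_width = 0.05, pseudocount = 1) {
  stopifnot(bin_width > 0, bin_width <= 2, pseudocount >= 0)
  breaks <- seq(-1, 1, by = bin_width)
  if (abs(breaks[length(breaks)] - 1) > 1e-9) breaks <- c(breaks, 1)
  r <- r[!is.na(r)]
  r <- pmin(pmax(r, -1), 1)
  counts <- graphics::hist(r, breaks = breaks, plot = FALSE)$counts + pseudocount
  p <- counts / sum(counts)
  attr(p, "breaks") <- breaks
  p
}

#' Kullback-Leibler divergence between binned distributions
#'
#' \eqn{D_{KL}(p \| q) = \sum_i p_i \log(p_i / q_i)} in nats. Used with the
#' data (or per-cell) histogram as p and a model histogram as q, both built
#' with [correlation_histogram()] on identical binning; the pseudocount there
#' guarantees a finite result.
#'
#' @param p,q Probability vectors of equal length.
#' @return Non-negative scalar (nats).
#' @export
#' @examples
#' kl_divergence(c(0.75, 0.25), c(0.5, 0.5))  # ~0.1308
kl_divergence <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must share binning")
  stopifnot(all(p >= 0), all(q >= 0))
  p <- p / sum(p); q <- q / sum(q)
  nz <- p > 0
  if (any(q[nz] == 0)) stop("q has zero mass where p does not; use a pseudocount")
  sum(p[nz] * log(p[nz] / q[nz]))
}

#' Bootstrapped major-axis (PCA) slope
#'
#' Slope of the first principal component of centered (x, y) pairs - the
#' total-least-squares line - expressed as dy/dx with the component oriented
#' to positive x loading. The standard error comes from bootstrap resampling
#' of the points. Used to ask whether inputs more correlated with the output
#' are also more selective (x = tuning correlation, y = vector strength).
#'
#' @param x,y Equal-length numeric vectors (>= 3 points, not all identical).
#' @param n_boot Bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @return List: `slope`, `se`, `n`, `boot` (the replicate slopes).
#' @export
pca_slope_bootstrap <- function(x, y, n_boot = 1000, seed = 1L) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  stopifnot(n >= 3, n_boot >= 100)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    stop("degenerate input: all points identical")
  }
  slope1 <- function(x, y) {
    v <- stats::prcomp(cbind(x, y), center = TRUE, scale. = FALSE)$rotation[, 1]
    if (v[1] < 0) v <- -v
    unname(v[2] / v[1])
  }
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    tryCatch(slope1(x[i], y[i]), error = function(e) NA_real_)
  }, numeric(1))
  list(slope = slope1(x, y), se = stats::sd(boot, na.rm = TRUE),
       n = n, boot = boot)
}

#' Trial variability at preferred and null orientations
#'
#' For every input, the trial-to-trial standard deviation of its
#' peak-normalized responses at its preferred stimulus and at the stimulus 90
#' degrees away (the "null"), summarized by population medians and IQRs and a
#' Wilcoxon rank-sum comparison. With Poisson-like (rate-scaled) variability,
#' null responses are reliably quieter than preferred ones.
#'
#' @param trial_responses Array n_trials x K x n_inputs (raw; normalization is
#'   applied internally per input).
#' @param grid Stimulus orientations (degrees, length K, equally spaced with
#'   even K so every stimulus has an orthogonal partner on the grid).
#' @param preferred_index Optional integer vector (length n_inputs) of each
#'   input's preferred stimulus index; defaults to the argmax of its
#'   trial-averaged curve.
#' @return List: `per_input` (data.frame: input, pref_index, null_index,
#'   pref_sd, null_sd), `summary` (medians and IQRs), `test`
#'   (wilcox.test result, two-sided).
#' @export
variability_by_orientation <- function(trial_responses, grid,
                                       preferred_index = NULL) {
  stopifnot(length(dim(trial_responses)) == 3,
            dim(trial_responses)[2] == length(grid),
            dim(trial_responses)[1] >= 2)
  K <- length(grid)
  if (K %% 2 != 0) stop("need an even stimulus grid so +90 deg lands on it")
  n <- dim(trial_responses)[3]
  if (is.null(preferred_index)) {
    preferred_index <- vapply(seq_len(n), function(s) {
      which.max(colMeans(trial_responses[, , s]))
    }, integer(1))
  }
  stopifnot(length(preferred_index) == n)
  null_index <- ((preferred_index - 1 + K / 2) %% K) + 1
  pref_sd <- numeric(n); null_sd <- numeric(n)
  for (s in seq_len(n)) {
    resp <- normalize_spine_responses(trial_responses[, , s])
    pref_sd[s] <- stats::sd(resp[, preferred_index[s]])
    null_sd[s] <- stats::sd(resp[, null_index[s]])
  }
  per_input <- data.frame(input = seq_len(n), pref_index = preferred_index,
                          null_index = null_index, pref_sd = pref_sd,
                          null_sd = null_sd)
  summ <- c(pref_median = stats::median(pref_sd), pref_iqr = stats::IQR(pref_sd),
            null_median = stats::median(null_sd), null_iqr = stats::IQR(null_sd))
  test <- stats::wilcox.test(null_sd, pref_sd)
  list(per_input = per_input, summary = summ, test = test)
}
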