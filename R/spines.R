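#' Generate a synthetic dendritic-spine imaging dataset
#'
#' Emulates the structure of a two-photon spine-imaging experiment on one
#' cell: gratings at 22.5-degree increments, 8-10 trials per stimulus,
#' DeltaF/F-like spine responses contaminated by a scaled copy of the global
#' dendritic (back-propagating action potential) signal, and blank-period
#' samples containing pure baseline noise. Ground-truth tuning parameters are
#' recorded for every spine so recovery can be tested.
#'
#' Spine responses are wrapped-Gaussian tuning curves plus additive Gaussian
#' noise plus `contamination * dendrite_signal`. The dendrite signal is the
#' soma's tuning curve plus its own trial noise. This generator reproduces the
#' *structure* of the recordings (trial counts, grids, blanks, contamination),
#' not the biophysics of calcium indicators.
#'
#' @param n_spines Number of spines (default 159, the average number of
#'   visually responsive spines per imaged cell).
#' @param n_trials Trials per stimulus, 8-10 in the experiments (default 10).
#' @param soma_pref Somatic preferred orientation, degrees.
#' @param pref_sd Dispersion (wrapped-normal SD, degrees) of spine preferred
#'   orientations around `soma_pref`; `Inf` draws uniform preferences.
#' @param amplitude_lognormal `c(meanlog=, sdlog=)` of spine response
#'   amplitudes.
#' @param baseline Mean spine baseline response.
#' @param width_range Range of tuning widths (Gaussian sigma, degrees) drawn
#'   uniformly.
#' @param noise_sd SD of the additive trial noise (same units as responses).
#' @param contamination_range Range of per-spine bAP contamination factors,
#'   drawn uniformly.
#' @param n_blank Blank-period samples per spine.
#' @param stimulus_step Grating increment in degrees (default 22.5).
#' @param seed Integer seed.
#' @return Object of class `"spine_dataset"`: `responses`
#'   (n_trials x K x n_spines raw spine signals), `blank`
#'   (n_blank x n_spines), `dendrite` (n_trials x K), `soma_tuning` (K),
#'   `stimulus_grid`, `ground_truth` (data.frame: pref_deg, amplitude,
#'   baseline, width_deg, contamination), `seed`.
#' @export
generate_spine_dataset <- function(n_spines = 159, n_trials = 10,
                                   soma_pref = 0, pref_sd = 35,
                                   amplitude_lognormal = c(meanlog = 0, sdlog = 0.4),
                                   baseline = 0.05,
                                   width_range = c(18, 35),
                                   noise_sd = 0.15,
                                   contamination_range = c(0, 0.4),
                                   n_blank = 40,
                                   stimulus_step = 22.5,
                                   seed = 1L) {
  stopifnot(n_spines >= 1, n_trials >= 2, n_blank >= 5,
            180 %% stimulus_step == 0)
  if (n_trials < 8 || n_trials > 10) {
    message("note: the imaging experiments used 8-10 trials per stimulus")
  }
  K <- as.integer(180 / stimulus_step)
  grid <- stimulus_grid(K)
  set.seed(seed)
  pref <- if (is.infinite(pref_sd)) {
    stats::runif(n_spines, -90, 90)
  } else {
    wrap_orientation(soma_pref + stats::rnorm(n_spines, 0, pref_sd))
  }
  amp <- stats::rlnorm(n_spines, amplitude_lognormal[["meanlog"]],
                       amplitude_lognormal[["sdlog"]])
  width <- stats::runif(n_spines, width_range[1], width_range[2])
  contam <- stats::runif(n_spines, contamination_range[1], contamination_range[2])

  soma_tuning <- exp(-orientation_diff(grid, soma_pref)^2 / (2 * 30^2))
  dendrite <- matrix(soma_tuning, n_trials, K, byrow = TRUE) +
    matrix(stats::rnorm(n_trials * K, 0, noise_sd), n_trials, K)

  arr <- array(NA_real_, dim = c(n_trials, K, n_spines))
  for (s in seq_len(n_spines)) {
    tun <- baseline + amp[s] * exp(-orientation_diff(grid, pref[s])^2 / (2 * width[s]^2))
    arr[, , s] <- matrix(tun, n_trials, K, byrow = TRUE) +
      matrix(stats::rnorm(n_trials * K, 0, noise_sd), n_trials, K) +
      contam[s] * dendrite
  }
  blank <- matrix(stats::rnorm(n_blank * n_spines, 0, noise_sd), n_blank, n_spines)
  structure(
    list(responses = arr, blank = blank, dendrite = dendrite,
         soma_tuning = soma_tuning, stimulus_grid = grid,
         ground_truth = data.frame(pref_deg = pref, amplitude = amp,
                                   baseline = baseline, width_deg = width,
                                   contamination = contam),
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "spine_dataset"
  )
}

#' @export
print.spine_dataset <- function(x, ...) {
  d <- dim(x$responses)
  cat(sprintf("spine_dataset: %d spines, %d trials x %d stimuli, %d blank samples each\n",
              d[3], d[1], d[2], nrow(x$blank)))
  invisible(x)
}

# Theil-Sen slope of y on x over all pairs (robust to sparse spiky outliers)
theil_sen_slope <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2) return(0)
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  ok <- abs(dx) > .Machine$double.eps^0.5
  if (!any(ok)) return(0)
  stats::median(dy[ok] / dx[ok])
}

#' Remove back-propagating action potentials from a spine signal
#'
#' Subtracts a scaled version of the dendritic signal from the spine signal.
#' The scale is a robust (Theil-Sen) slope of spine on dendrite, clipped at
#' zero. When the signals are trials x stimuli matrices, the slope is
#' estimated on within-stimulus residuals (each column demeaned): bAP
#' contamination is a trial-by-trial coupling, whereas the across-stimulus
#' components of spine and dendrite both carry orientation tuning and would
#' confound the scale whenever the spine is co-tuned with the soma. The
#' rank-based slope additionally resists sparse, spiky contamination events.
#' A constant dendrite signal yields scale 0 and leaves the spine unchanged.
#'
#' @param spine_signal,dendrite_signal Equal-shaped numeric vectors/matrices.
#' @return List with `corrected` (same shape as `spine_signal`) and `scale`.
#' @export
#' @examples
#' d <- sin(1:40); s <- 0.7 * d
#' subtract_bap(s, d)$scale  # ~0.7
subtract_bap <- function(spine_signal, dendrite_signal) {
  if (!identical(dim(spine_signal), dim(dendrite_signal)) ||
      length(spine_signal) != length(dendrite_signal)) {
    stop("'spine_signal' and 'dendrite_signal' must have identical shape")
  }
  if (is.matrix(spine_signal)) {
    x <- as.numeric(sweep(dendrite_signal, 2, colMeans(dendrite_signal)))
    y <- as.numeric(sweep(spine_signal, 2, colMeans(spine_signal)))
  } else {
    x <- as.numeric(dendrite_signal)
    y <- as.numeric(spine_signal)
  }
  s <- if (stats::sd(x) < .Machine$double.eps^0.5) 0 else theil_sen_slope(x, y)
  s <- max(s, 0)
  list(corrected = spine_signal - s * dendrite_signal, scale = s)
}

#' Spine inclusion quality-control filter
#'
#' Applies the two inclusion criteria used for imaged spines, after bAP
#' subtraction: (1) SNR - the mean response at the preferred stimulus must
#' exceed the blank-period median by more than two (unscaled) median absolute
#' deviations of the blank noise; (2) independence from the dendrite - the
#' Spearman correlation between the corrected spine signal and the dendritic
#' signal, computed ignoring time points where the corrected signal is
#' negative, must be below `cor_threshold`. Spines with fewer than
#' `min_usable` usable points for the correlation are flagged indeterminate
#' and excluded.
#'
#' @param dataset A [generate_spine_dataset()] result (or compatible list).
#' @param snr_mads Number of blank MADs above the blank median required
#'   (default 2).
#' @param cor_threshold Maximum allowed Spearman correlation with the
#'   dendrite (default 0.4).
#' @param min_usable Minimum usable samples for the correlation (default 3).
#' @return data.frame (class `"spine_qc_report"`), one row per spine:
#'   `spine`, `snr_stat`, `snr_threshold`, `pass_snr`, `dendrite_cor`,
#'   `pass_cor`, `usable_n`, `pass`, `reason`.
#' @export
spine_inclusion_filter <- function(dataset, snr_mads = 2, cor_threshold = 0.4,
                                   min_usable = 3) {
  stopifnot(inherits(dataset, "spine_dataset") ||
              (is.list(dataset) && !is.null(dataset$responses) &&
                 !is.null(dataset$blank) && !is.null(dataset$dendrite)))
  n_spines <- dim(dataset$responses)[3]
  den <- dataset$dendrite
  out <- vector("list", n_spines)
  for (s in seq_len(n_spines)) {
    raw <- dataset$responses[, , s]
    sub <- subtract_bap(raw, den)
    corr <- sub$corrected
    blank <- dataset$blank[, s]
    thr <- stats::median(blank) + snr_mads * stats::mad(blank, constant = 1)
    snr_stat <- max(colMeans(corr))
    pass_snr <- snr_stat > thr
    keep <- as.numeric(corr) >= 0
    usable <- sum(keep)
    if (usable < min_usable) {
      cor_d <- NA_real_
      pass_cor <- FALSE
      reason <- "indeterminate_correlation"
    } else {
      cor_d <- suppressWarnings(
        stats::cor(as.numeric(corr)[keep], as.numeric(den)[keep],
                   method = "spearman"))
      if (is.na(cor_d)) cor_d <- 0  # flat corrected signal: no dendrite coupling
      pass_cor <- cor_d < cor_threshold
      reason <- if (pass_snr && pass_cor) "ok"
        else paste(c(if (!pass_snr) "low_snr",
                     if (!pass_cor) "dendrite_correlated"), collapse = "+")
    }
    out[[s]] <- data.frame(spine = s, snr_stat = snr_stat, snr_threshold = thr,
                           pass_snr = pass_snr, dendrite_cor = cor_d,
                           pass_cor = pass_cor, usable_n = usable,
                           pass = pass_snr && pass_cor, reason = reason)
  }
  res <- do.call(rbind, out)
  class(res) <- c("spine_qc_report", class(res))
  res
}

#' Fit a wrapped-Gaussian orientation tuning curve
#'
#' Nonlinear least-squares fit of
#' \eqn{b + a \exp\{-d(\theta, p)^2 / (2 w^2)\}} to trial responses, where
#' \eqn{d} is the wrapped orientation difference in degrees. Multi-start over
#' a grid of preferred orientations (and two widths) guards against local
#' minima; the best-RSS converged fit wins. If no start converges, the
#' preferred orientation falls back to the circular mean of the responses and
#' `converged` is FALSE. Near-constant responses are flagged degenerate.
#'
#' @param responses Trials x K matrix, or a length-K vector of trial-averaged
#'   responses.
#' @param grid Stimulus orientations (degrees), length K >= 4 distinct values.
#' @return List of class `"tuning_fit"`: `pref_deg` in [-90, 90), `amplitude`,
#'   `width_deg`, `baseline`, `rss`, `converged`.
#' @export
fit_tuning_gaussian <- function(responses, grid) {
  if (is.matrix(responses)) {
    stopifnot(ncol(responses) == length(grid))
    y <- colMeans(responses)
  } else {
    stopifnot(length(responses) == length(grid))
    y <- as.numeric(responses)
  }
  if (length(unique(round(grid, 9))) < 4) {
    stop("need >= 4 distinct stimulus values")
  }
  circ_mean <- wrap_orientation(
    0.5 * atan2(sum(y * sin(2 * grid * pi / 180)),
                sum(y * cos(2 * grid * pi / 180))) * 180 / pi)
  if (stats::sd(y) < 1e-12) {
    return(structure(list(pref_deg = circ_mean, amplitude = 0,
                          width_deg = NA_real_, baseline = mean(y),
                          rss = 0, converged = FALSE),
                     class = "tuning_fit"))
  }
  df <- data.frame(theta = grid, y = y)
  best <- NULL
  for (p0 in grid) for (w0 in c(15, 30)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ b + a * exp(-orientation_diff(theta, p)^2 / (2 * w^2)),
        data = df,
        start = list(b = min(y), a = max(y) - min(y), p = p0, w = w0),
        lower = c(b = -Inf, a = 0, p = -270, w = 4),
        upper = c(b = Inf, a = Inf, p = 270, w = 85),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- stats::coef(fit)
      best <- list(pref_deg = wrap_orientation(cf[["p"]]),
                   amplitude = cf[["a"]], width_deg = cf[["w"]],
                   baseline = cf[["b"]], rss = rss, converged = TRUE)
    }
  }
  if (is.null(best)) {
    best <- list(pref_deg = circ_mean, amplitude = NA_real_,
                 width_deg = NA_real_, baseline = mean(y),
                 rss = NA_real_, converged = FALSE)
  }
  structure(best, class = "tuning_fit")
}

#' @export
print.tuning_fit <- function(x, ...) {
  cat(sprintf("tuning_fit: pref %.1f deg, amp %.3g, width %.1f deg, baseline %.3g (%s)\n",
              x$pref_deg, x$amplitude, x$width_deg, x$baseline,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Vector strength of an orientation tuning curve
#'
#' Circular-resultant selectivity index on the doubled-angle (orientation)
#' circle: \eqn{v = |\sum_k r_k e^{2 i \theta_k}| / \sum_k r_k}. A neuron
#' responding to a single orientation scores 1; equal responses at all
#' orientations of a uniform grid score 0. Negative mean responses are floored
#' at zero with a warning (DeltaF/F estimates can dip below baseline).
#'
#' @param responses Mean response per stimulus (length K).
#' @param grid Stimulus orientations, degrees.
#' @return Scalar in [0, 1].
#' @export
#' @examples
#' vector_strength(c(2, 1, 0, 1), c(-90, -45, 0, 45))  # 0.5
vector_strength <- function(responses, grid) {
  stopifnot(length(responses) == length(grid))
  if (any(responses < 0)) {
    warning("negative responses floored at 0 for vector strength")
    responses <- pmax(responses, 0)
  }
  tot <- sum(responses)
  if (tot <= 0) stop("vector_strength undefined: responses sum to zero")
  a2 <- 2 * grid * pi / 180
  sqrt(sum(responses * cos(a2))^2 + sum(responses * sin(a2))^2) / tot
}

#' Normalize spine responses to unit peak
#'
#' Divides all of a spine's trial responses by the peak of its trial-averaged
#' tuning curve, so every spine carries equal weight in population analyses
#' (peak of the mean curve = 1).
#'
#' @param responses Trials x K matrix of one spine's responses.
#' @return The rescaled matrix, with the scale factor in attribute `"peak"`.
#' @export
normalize_spine_responses <- function(responses) {
  stopifnot(is.matrix(responses))
  peak <- max(colMeans(responses))
  if (!is.finite(peak) || peak <= 0) {
    stop("normalize_spine_responses(): peak mean response must be positive")
  }
  out <- responses / peak
  attr(out, "peak") <- peak
  out
}
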