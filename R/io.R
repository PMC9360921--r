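# Full-precision serialization: 17 significant digits round-trip doubles
fmt_full <- function(x) {
  if (is.double(x)) formatC(x, digits = 17, format = "g") else x
}

#' Write a data.frame as full-precision CSV
#'
#' Doubles are written with 17 significant digits so that reading the file
#' back reproduces them bit for bit.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_full <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt_full), stringsAsFactors = FALSE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize an input population
#'
#' Writes `<prefix>_neurons.csv` (one row per neuron: alpha, beta, kappa,
#' phi_deg) and `<prefix>_spec.json` (population spec). The correlation and
#' covariance matrices are deterministic functions of these and are rebuilt on
#' read; set `covariance = TRUE` to also write the dense covariance.
#'
#' @param pop An input population.
#' @param prefix Path prefix.
#' @param covariance Also write `<prefix>_covariance.csv`? Default FALSE.
#' @return Character vector of the files written.
#' @export
write_population <- function(pop, prefix, covariance = FALSE) {
  stopifnot(inherits(pop, "input_population"))
  np <- paste0(prefix, "_neurons.csv")
  write_table_full(pop$neurons[c("alpha", "beta", "kappa", "phi_deg")], np)
  sp <- paste0(prefix, "_spec.json")
  spec <- pop$spec
  spec_json <- list(
    n_neurons = spec$n_neurons, kind = spec$kind,
    max_correlation = spec$max_correlation, n_stimuli = spec$n_stimuli,
    homogeneous_params = as.list(spec$homogeneous_params),
    bandwidth_lognormal = as.list(spec$bandwidth_lognormal),
    amplitude_lognormal = as.list(spec$amplitude_lognormal),
    baseline_exp_mean = spec$baseline_exp_mean, seed = spec$seed)
  jsonlite::write_json(spec_json, sp, auto_unbox = TRUE, digits = NA)
  files <- c(np, sp)
  if (covariance) {
    cp <- paste0(prefix, "_covariance.csv")
    write_table_full(as.data.frame(pop$covariance), cp)
    files <- c(files, cp)
  }
  files
}

#' Read an input population written by [write_population()]
#'
#' @param prefix The path prefix used when writing.
#' @return An `"input_population"` equal to the one written (matrices are
#'   rebuilt deterministically from the per-neuron parameters).
#' @export
read_population <- function(prefix) {
  neurons <- utils::read.csv(paste0(prefix, "_neurons.csv"))
  sj <- jsonlite::read_json(paste0(prefix, "_spec.json"), simplifyVector = TRUE)
  spec <- population_spec(
    n_neurons = sj$n_neurons, kind = sj$kind,
    max_correlation = sj$max_correlation, n_stimuli = sj$n_stimuli,
    homogeneous_params = unlist(sj$homogeneous_params),
    bandwidth_lognormal = unlist(sj$bandwidth_lognormal),
    amplitude_lognormal = unlist(sj$amplitude_lognormal),
    baseline_exp_mean = sj$baseline_exp_mean, seed = sj$seed)
  fm <- tuning_matrix(spec$stimulus_grid, neurons$alpha, neurons$beta,
                      neurons$kappa, neurons$phi_deg)
  mu <- colMeans(fm)
  C <- build_correlation_matrix(neurons$phi_deg, spec$max_correlation)
  Q <- suppressWarnings(scale_to_covariance(C, mu))
  jitter <- 0
  ok <- tryCatch({ chol(Q); TRUE }, error = function(e) FALSE)
  if (!ok) {
    jitter <- 1e-8 * sum(diag(Q)) / nrow(neurons)
    Q <- Q + diag(jitter, nrow(neurons))
  }
  neurons$mean_rate <- mu
  structure(
    list(neurons = neurons, stimulus_grid = spec$stimulus_grid,
         mean_response = fm, correlation = C, covariance = Q,
         jitter = jitter, spec = spec),
    class = "input_population")
}

#' Serialize decoder weights
#'
#' Writes a CSV with one row per stimulus class (`stimulus_deg`, `offset`,
#' `prior`, `w_1` ... `w_N`) plus a JSON sidecar (`<path>.json`) with the
#' provenance and solve residual.
#'
#' @param weights A `"decoder_weights"` object.
#' @param path CSV output path.
#' @return Character vector of the files written.
#' @export
write_weights <- function(weights, path) {
  stopifnot(inherits(weights, "decoder_weights"))
  W <- as.data.frame(weights$weights)
  names(W) <- paste0("w_", seq_len(ncol(W)))
  df <- cbind(data.frame(stimulus_deg = weights$stimulus_grid,
                         offset = weights$offsets, prior = weights$prior), W)
  write_table_full(df, path)
  side <- paste0(path, ".json")
  jsonlite::write_json(list(provenance = weights$provenance,
                            max_residual = weights$max_residual),
                       side, auto_unbox = TRUE, digits = NA)
  c(path, side)
}

#' Read decoder weights written by [write_weights()]
#'
#' @param path The CSV path used when writing.
#' @return A `"decoder_weights"` object.
#' @export
read_weights <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  wcols <- grep("^w_", names(df))
  structure(
    list(weights = unname(as.matrix(df[, wcols])),
         offsets = df$offset, prior = df$prior,
         stimulus_grid = df$stimulus_deg,
         provenance = side$provenance,
         max_residual = if (is.null(side$max_residual)) NA_real_ else side$max_residual),
    class = "decoder_weights")
}

#' Serialize a spine dataset as tidy CSV tables
#'
#' The documented exchange schema for spine-imaging data. Writes
#' `<prefix>_responses.csv` (spine, stimulus_deg, trial, response),
#' `<prefix>_blank.csv` (spine, sample, response),
#' `<prefix>_dendrite.csv` (trial, stimulus_deg, response) and
#' `<prefix>_meta.json` (stimulus grid, soma tuning, ground truth if present,
#' seed). Real recordings exported in this schema can be read with
#' [read_spine_dataset()] and passed through the same QC and analysis
#' pipeline as synthetic data.
#'
#' @param dataset A `"spine_dataset"`.
#' @param prefix Path prefix.
#' @return Character vector of the files written.
#' @export
write_spine_dataset <- function(dataset, prefix) {
  d <- dim(dataset$responses)
  tidy <- data.frame(
    spine = rep(seq_len(d[3]), each = d[1] * d[2]),
    stimulus_deg = rep(rep(dataset$stimulus_grid, each = d[1]), d[3]),
    trial = rep(seq_len(d[1]), d[2] * d[3]),
    response = as.numeric(dataset$responses))
  rp <- paste0(prefix, "_responses.csv")
  write_table_full(tidy, rp)
  bp <- paste0(prefix, "_blank.csv")
  write_table_full(data.frame(
    spine = rep(seq_len(ncol(dataset$blank)), each = nrow(dataset$blank)),
    sample = rep(seq_len(nrow(dataset$blank)), ncol(dataset$blank)),
    response = as.numeric(dataset$blank)), bp)
  dp <- paste0(prefix, "_dendrite.csv")
  write_table_full(data.frame(
    trial = rep(seq_len(nrow(dataset$dendrite)), ncol(dataset$dendrite)),
    stimulus_deg = rep(dataset$stimulus_grid, each = nrow(dataset$dendrite)),
    response = as.numeric(dataset$dendrite)), dp)
  mp <- paste0(prefix, "_meta.json")
  meta <- list(stimulus_grid = dataset$stimulus_grid,
               soma_tuning = dataset$soma_tuning,
               noise_sd = dataset$noise_sd, seed = dataset$seed)
  if (!is.null(dataset$ground_truth)) meta$ground_truth <- dataset$ground_truth
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA)
  c(rp, bp, dp, mp)
}

#' Read a spine dataset written in the tidy CSV schema
#'
#' @param prefix The path prefix used by [write_spine_dataset()].
#' @return A `"spine_dataset"`.
#' @export
read_spine_dataset <- function(prefix) {
  tidy <- utils::read.csv(paste0(prefix, "_responses.csv"))
  blank <- utils::read.csv(paste0(prefix, "_blank.csv"))
  den <- utils::read.csv(paste0(prefix, "_dendrite.csv"))
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  grid <- meta$stimulus_grid
  n_spines <- max(tidy$spine)
  n_trials <- max(tidy$trial)
  K <- length(grid)
  tidy <- tidy[order(tidy$spine, match(tidy$stimulus_deg, grid), tidy$trial), ]
  arr <- array(tidy$response, dim = c(n_trials, K, n_spines))
  blank <- blank[order(blank$spine, blank$sample), ]
  bm <- matrix(blank$response, nrow = max(blank$sample), ncol = n_spines)
  den <- den[order(match(den$stimulus_deg, grid), den$trial), ]
  dm <- matrix(den$response, nrow = max(den$trial), ncol = K)
  structure(
    list(responses = arr, blank = bm, dendrite = dm,
         soma_tuning = meta$soma_tuning, stimulus_grid = grid,
         ground_truth = meta$ground_truth,
         noise_sd = meta$noise_sd, seed = meta$seed),
    class = "spine_dataset")
}
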