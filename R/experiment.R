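#' Derive reproducible child seeds from a master seed
#'
#' All multi-stage experiments draw their per-stage seeds from the master seed
#' through this one function, so a single integer reproduces an entire run.
#' Seeds are drawn without replacement from the 31-bit integer range.
#'
#' @param master Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(master, n) {
  stopifnot(length(master) == 1, is.finite(master), n >= 1)
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate the synapse-versus-readout comparison experiment
#'
#' The model side of the spine-imaging comparison, run end to end: build an
#' input population, derive the analytic decoder weights, turn each decoder
#' neuron's positive weights into a synaptic input population, simulate noisy
#' trials on the coarse experimental grid, and correlate every synapse's
#' trial-averaged tuning with its decoder neuron's output tuning. Repeated
#' `n_runs` times with independent populations; every decoder neuron (one per
#' stimulus class) counts as one simulated "cell".
#'
#' @param kind `"homogeneous"` or `"heterogeneous"`.
#' @param n_runs Number of independent simulation runs.
#' @param n_neurons Input population size (default 1000).
#' @param max_correlation Maximum pairwise noise correlation (default 0.20).
#' @param n_synapses Synapses sampled per decoder neuron (default 100).
#' @param n_trials Simulated trials per stimulus (default 10).
#' @param n_stimuli Stimulus classes / grid size (default 8: 22.5-degree
#'   increments, matching the imaging protocol).
#' @param replace Sample synapses with replacement? Default FALSE.
#' @param noise_model Trial-noise model, see [simulate_synaptic_trials()].
#' @param seed Master seed.
#' @return List of class `"synapse_comparison"`:
#'   `per_synapse` (data.frame: run, cell, synapse, source, r, vstrength,
#'   pref_sd, null_sd), `per_cell` (run, cell, mean_r, n_valid),
#'   `summary` (pooled_median_r, cell_median_r, pref_sd_median,
#'   null_sd_median, n_synapses, n_cells), and the call parameters.
#' @export
run_synapse_comparison <- function(kind = c("homogeneous", "heterogeneous"),
                                   n_runs = 200,
                                   n_neurons = 1000,
                                   max_correlation = 0.20,
                                   n_synapses = 100,
                                   n_trials = 10,
                                   n_stimuli = 8,
                                   replace = FALSE,
                                   noise_model = "shared_plus_rate",
                                   seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n_runs >= 1)
  run_seeds <- derive_seeds(seed, n_runs)
  syn_rows <- vector("list", n_runs)
  cell_rows <- vector("list", n_runs)
  K <- n_stimuli
  for (i in seq_len(n_runs)) {
    sub_seeds <- derive_seeds(run_seeds[i], 1 + 2 * K)
    spec <- population_spec(n_neurons, kind, max_correlation,
                            n_stimuli = n_stimuli, seed = sub_seeds[1])
    pop <- make_population(spec)
    w <- derive_weights(pop)
    out_tuning <- decoder_output_tuning(w, pop)  # K_stim x K_class
    sr <- vector("list", K)
    cr <- vector("list", K)
    for (k in seq_len(K)) {
      probs <- weights_to_frequency(w$weights[k, ])
      syn <- sample_synapses(pop, probs, n_synapses = n_synapses,
                             stimulus_grid = pop$stimulus_grid,
                             replace = replace, seed = sub_seeds[2 * k])
      syn <- simulate_synaptic_trials(syn, pop, n_trials = n_trials,
                                      seed = sub_seeds[2 * k + 1],
                                      noise_model = noise_model,
                                      weights = w, class_index = k)
      mean_curves <- t(colMeans(syn$trial_responses))       # n_syn x K
      cd <- correlation_distribution(mean_curves, syn$decoder_output)
      vs <- vapply(seq_len(n_synapses), function(s) {
        vector_strength(pmax(mean_curves[s, ], 0), syn$stimulus_grid)
      }, numeric(1))
      pref_idx <- apply(syn$tuning, 1, which.max)           # ground-truth peak
      vb <- variability_by_orientation(syn$trial_responses, syn$stimulus_grid,
                                       preferred_index = pref_idx)
      sr[[k]] <- data.frame(run = i, cell = k,
                            synapse = seq_len(n_synapses),
                            source = syn$source_indices,
                            r = cd$r, vstrength = vs,
                            pref_sd = vb$per_input$pref_sd,
                            null_sd = vb$per_input$null_sd)
      cr[[k]] <- data.frame(run = i, cell = k, mean_r = cd$mean_r,
                            n_valid = n_synapses - cd$n_excluded)
    }
    syn_rows[[i]] <- do.call(rbind, sr)
    cell_rows[[i]] <- do.call(rbind, cr)
  }
  per_synapse <- do.call(rbind, syn_rows)
  per_cell <- do.call(rbind, cell_rows)
  structure(
    list(per_synapse = per_synapse, per_cell = per_cell,
         summary = c(pooled_median_r = stats::median(per_synapse$r, na.rm = TRUE),
                     cell_median_r = stats::median(per_cell$mean_r, na.rm = TRUE),
                     pref_sd_median = stats::median(per_synapse$pref_sd, na.rm = TRUE),
                     null_sd_median = stats::median(per_synapse$null_sd, na.rm = TRUE)),
         kind = kind, n_runs = n_runs, n_neurons = n_neurons,
         max_correlation = max_correlation, n_synapses = n_synapses,
         n_trials = n_trials, n_stimuli = n_stimuli, replace = replace,
         noise_model = noise_model, seed = seed),
    class = "synapse_comparison"
  )
}

#' @export
print.synapse_comparison <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("synapse_comparison (%s, %d runs x %d cells):\n",
           "  pooled median r        = %.3f\n",
           "  median per-cell mean r = %.3f\n",
           "  median trial s.d.: preferred = %.3f, null = %.3f\n"),
    x$kind, x$n_runs, x$n_stimuli,
    s[["pooled_median_r"]], s[["cell_median_r"]],
    s[["pref_sd_median"]], s[["null_sd_median"]]))
  invisible(x)
}

#' Run a named experiment and write its artifacts
#'
#' Orchestrates the package's three standard experiments and serializes their
#' outputs (full-precision CSV tables plus a JSON run manifest recording the
#' configuration, every derived seed and every artifact path). Re-running the
#' same configuration reproduces the CSV outputs byte for byte.
#'
#' Experiments:
#' \describe{
#'   \item{`weights`}{Build a homogeneous and a heterogeneous population,
#'     derive analytic weights, optionally smooth them; writes population and
#'     weight tables.}
#'   \item{`accuracy-sweep`}{[accuracy_sweep()] over the configured grids;
#'     writes the tidy sweep table.}
#'   \item{`synapse-comparison`}{[run_synapse_comparison()] for both
#'     population kinds; writes per-synapse and per-cell tables and a summary.}
#' }
#'
#' @param config A list (or path to a JSON file) with elements `experiment`
#'   (one of the names above), `out_dir`, `seed`, and an optional `params`
#'   list overriding experiment defaults.
#' @return The manifest (invisibly), also written to
#'   `file.path(out_dir, "manifest.json")`.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config), !is.null(config$experiment), !is.null(config$out_dir))
  experiment <- match.arg(config$experiment,
                          c("weights", "accuracy-sweep", "synapse-comparison"))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  params <- if (is.null(config$params)) list() else config$params
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  stage_seeds <- derive_seeds(seed, 8)

  if (experiment == "weights") {
    n <- params$n_neurons %||% 1000
    c_o <- params$max_correlation %||% 0.25
    K <- params$n_stimuli %||% 8
    smoothing <- params$smoothing %||% list()
    for (kind in c("homogeneous", "heterogeneous")) {
      sd_k <- stage_seeds[if (kind == "homogeneous") 1 else 2]
      pop <- make_population(population_spec(n, kind, c_o, n_stimuli = K, seed = sd_k))
      w <- derive_weights(pop)
      pp <- file.path(out_dir, paste0("population_", kind))
      artifacts <- c(artifacts, write_population(pop, pp))
      wp <- file.path(out_dir, paste0("weights_", kind, ".csv"))
      artifacts <- c(artifacts, write_weights(w, wp))
      for (rho in smoothing) {
        ws <- smooth_weights(w, pop, rho[1], rho[2])
        sp <- file.path(out_dir, sprintf("weights_%s_smoothed_%g_%g.csv",
                                         kind, rho[1], rho[2]))
        artifacts <- c(artifacts, write_weights(ws, sp))
      }
    }
  } else if (experiment == "accuracy-sweep") {
    sw <- accuracy_sweep(
      kinds = params$kinds %||% c("homogeneous", "heterogeneous"),
      n_grid = params$n_grid %||% 2^(2:9),
      c_o_grid = params$c_o_grid %||% c(0, 0.25, 0.5),
      smoothing_grid = params$smoothing_grid %||% list(c(0, 0)),
      n_seeds = params$n_seeds %||% 5,
      n_stimuli = params$n_stimuli %||% 120,
      trials_per_stimulus = params$trials_per_stimulus %||% 20,
      seed = stage_seeds[1])
    p <- file.path(out_dir, "accuracy_sweep.csv")
    write_table_full(sw, p)
    artifacts <- c(artifacts, p)
  } else {
    summaries <- list()
    for (kind in c("homogeneous", "heterogeneous")) {
      sd_k <- stage_seeds[if (kind == "homogeneous") 1 else 2]
      cmp <- run_synapse_comparison(
        kind = kind,
        n_runs = params$n_runs %||% 200,
        n_neurons = params$n_neurons %||% 1000,
        max_correlation = params$max_correlation %||% 0.20,
        n_synapses = params$n_synapses %||% 100,
        n_trials = params$n_trials %||% 10,
        n_stimuli = params$n_stimuli %||% 8,
        seed = sd_k)
      for (tbl in c("per_synapse", "per_cell")) {
        p <- file.path(out_dir, sprintf("%s_%s.csv", kind, tbl))
        write_table_full(cmp[[tbl]], p)
        artifacts <- c(artifacts, p)
      }
      summaries[[kind]] <- as.list(cmp$summary)
    }
    p <- file.path(out_dir, "comparison_summary.json")
    jsonlite::write_json(summaries, p, auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, p)
  }

  manifest <- list(experiment = experiment, config = config, seed = seed,
                   stage_seeds = stage_seeds, artifacts = artifacts,
                   package_version = as.character(utils::packageVersion("popdecode")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
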