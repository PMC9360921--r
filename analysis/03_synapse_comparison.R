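#!/usr/bin/env Rscript
# The synaptic-population comparison: resample each decoder neuron's positive
# weights into 100 synapses, simulate noisy trials on the 22.5-degree grid,
# and compare input tuning with readout tuning. Writes per-synapse and
# per-cell tables plus a JSON summary under results/comparison/, then
# computes the distribution-level statistics (medians, KL model
# identification, selectivity slope, null/preferred variability).
#
# Optional argument: number of runs per model (default 200).

suppressPackageStartupMessages(library(popdecode))

n_runs <- {
  a <- commandArgs(trailingOnly = TRUE)
  if (length(a) >= 1) as.integer(a[1]) else 200L
}
out_dir <- "results/comparison"
manifest <- run_experiment(list(
  experiment = "synapse-comparison", out_dir = out_dir, seed = 40,
  params = list(n_runs = n_runs)))

cmp <- lapply(c("homogeneous", "heterogeneous"), function(kind) {
  list(per_synapse = read.csv(file.path(out_dir, paste0(kind, "_per_synapse.csv"))),
       per_cell = read.csv(file.path(out_dir, paste0(kind, "_per_cell.csv"))))
})
names(cmp) <- c("homogeneous", "heterogeneous")

cat(sprintf("synapse-output tuning correlations (%d runs x 8 cells x 100 synapses per model):\n",
            n_runs))
for (kind in names(cmp)) {
  ps <- cmp[[kind]]$per_synapse; pc <- cmp[[kind]]$per_cell
  cat(sprintf("  %-13s pooled median r = %.3f, median per-cell mean r = %.3f\n",
              kind, median(ps$r, na.rm = TRUE), median(pc$mean_r, na.rm = TRUE)))
}

# KL-based model identification, self-consistency at bin width 0.05
ref <- lapply(cmp, function(x) correlation_histogram(x$per_synapse$r))
for (kind in names(cmp)) {
  ps <- cmp[[kind]]$per_synapse
  cells <- split(ps$r, interaction(ps$run, ps$cell, drop = TRUE))
  closer <- vapply(cells, function(r) {
    p <- correlation_histogram(r)
    kl_divergence(p, ref[[kind]]) <
      kl_divergence(p, ref[[setdiff(names(cmp), kind)]])
  }, logical(1))
  cat(sprintf("  %-13s cells closer to their own model by D_KL: %.1f%%\n",
              kind, 100 * mean(closer)))
}

# does selectivity predict the input-output correlation?
for (kind in names(cmp)) {
  ps <- cmp[[kind]]$per_synapse
  sl <- pca_slope_bootstrap(ps$r, ps$vstrength, n_boot = 1000, seed = 41)
  cat(sprintf("  %-13s PCA slope (r vs vector strength) = %.4f +/- %.4f s.e.\n",
              kind, sl$slope, sl$se))
}

# trial variability at null vs preferred orientations (heterogeneous model)
ps <- cmp$heterogeneous$per_synapse
wt <- wilcox.test(ps$null_sd, ps$pref_sd)
cat(sprintf("  null vs preferred trial s.d. (het): median %.3f vs %.3f, rank-sum p = %.3g\n",
            median(ps$null_sd, na.rm = TRUE), median(ps$pref_sd, na.rm = TRUE),
            wt$p.value))

cat("\nFinding: homogeneous readouts collect mostly co-tuned synapses (high\n")
cat("input-output correlation); heterogeneous readouts produce the diverse,\n")
cat("weakly correlated synaptic tuning seen in imaged spine populations,\n")
cat("with quieter responses at null orientations than at preferred ones.\n")
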