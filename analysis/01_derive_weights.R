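#!/usr/bin/env Rscript
# Analytic decoder weights for homogeneous vs heterogeneous input populations
# (N = 1000, moderate limited-range correlation c_o = 0.25), plus the effect
# of progressively smoothing a heterogeneous weight vector. Writes the
# population and weight tables under results/weights/.

suppressPackageStartupMessages(library(popdecode))

out_dir <- "results/weights"
manifest <- run_experiment(list(
  experiment = "weights", out_dir = out_dir, seed = 20,
  params = list(n_neurons = 1000, max_correlation = 0.25, n_stimuli = 8,
                smoothing = list(c(0.1, 1), c(0.2, 2), c(1, 10)))))

# narrative: quantify the qualitative weight structure
hf <- function(w, pop, k = 5) {
  o <- order(pop$neurons$phi_deg)
  var(diff(w$weights[k, o]))
}
for (kind in c("homogeneous", "heterogeneous")) {
  pop <- read_population(file.path(out_dir, paste0("population_", kind)))
  w <- read_weights(file.path(out_dir, paste0("weights_", kind, ".csv")))
  k <- 5  # decoder neuron preferring 0 degrees
  wk <- w$weights[k, ]
  d <- orientation_diff(pop$neurons$phi_deg, 0)
  cat(sprintf("\n%s population (N = %d, c_o = 0.25):\n", kind, length(wk)))
  cat(sprintf("  mean weight at |dphi| < 10 deg : %8.4f\n", mean(wk[d < 10])))
  cat(sprintf("  mean weight at 15-35 deg       : %8.4f (flank)\n",
              mean(wk[d >= 15 & d <= 35])))
  cat(sprintf("  mean weight at |dphi| > 80 deg : %8.4f (orthogonal)\n",
              mean(wk[d > 80])))
  cat(sprintf("  high-frequency content (var of first differences): %.4g\n",
              hf(w, pop)))
}

cat("\nsmoothing a heterogeneous weight vector:\n")
pop <- read_population(file.path(out_dir, "population_heterogeneous"))
w0 <- read_weights(file.path(out_dir, "weights_heterogeneous.csv"))
cat(sprintf("  (0,0)    high-frequency content: %.4g\n", hf(w0, pop)))
for (rho in list(c(0.1, 1), c(0.2, 2), c(1, 10))) {
  ws <- read_weights(file.path(
    out_dir, sprintf("weights_heterogeneous_smoothed_%g_%g.csv", rho[1], rho[2])))
  cat(sprintf("  (%g,%g) high-frequency content: %.4g\n",
              rho[1], rho[2], hf(ws, pop)))
}
cat("\nFinding: homogeneous weights vary smoothly over orientation preference\n")
cat("(central peak, negative flanks, near-zero orthogonal weights), while\n")
cat("heterogeneous weights carry strong neuron-to-neuron variation at every\n")
cat("orientation; smoothing removes that variation progressively.\n")
cat("Artifacts:", paste(manifest$artifacts, collapse = "\n  "), "\n")
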