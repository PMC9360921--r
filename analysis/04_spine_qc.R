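#!/usr/bin/env Rscript
# Synthetic spine-imaging dataset through the experimental analysis pipeline:
# bAP subtraction, inclusion QC, peak normalization, Gaussian tuning fits and
# vector strengths, then the spine-versus-soma correlation distribution.
# Writes the dataset (tidy CSV schema), QC report and fit table under
# results/spines/.

suppressPackageStartupMessages(library(popdecode))

out_dir <- "results/spines"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

ds <- generate_spine_dataset(seed = 50)  # 159 spines, 10 trials, 22.5-deg grid
write_spine_dataset(ds, file.path(out_dir, "synthetic_cell"))

qc <- spine_inclusion_filter(ds)
write_table_full(as.data.frame(qc), file.path(out_dir, "qc_report.csv"))
cat(sprintf("QC: %d / %d spines pass (%d low SNR, %d dendrite-correlated, %d indeterminate)\n",
            sum(qc$pass), nrow(qc), sum(!qc$pass_snr),
            sum(qc$pass_snr & !qc$pass_cor & qc$reason != "indeterminate_correlation"),
            sum(qc$reason == "indeterminate_correlation")))

keep <- which(qc$pass)
fits <- vector("list", length(keep))
vs <- numeric(length(keep))
rr <- numeric(length(keep))
for (j in seq_along(keep)) {
  s <- keep[j]
  corr <- subtract_bap(ds$responses[, , s], ds$dendrite)$corrected
  norm <- normalize_spine_responses(corr)
  fit <- fit_tuning_gaussian(norm, ds$stimulus_grid)
  fits[[j]] <- data.frame(spine = s, pref_deg = fit$pref_deg,
                          amplitude = fit$amplitude, width_deg = fit$width_deg,
                          baseline = fit$baseline, converged = fit$converged,
                          true_pref_deg = ds$ground_truth$pref_deg[s])
  vs[j] <- vector_strength(pmax(colMeans(norm), 0), ds$stimulus_grid)
  rr[j] <- tuning_correlation(colMeans(norm), ds$soma_tuning)
}
fits <- do.call(rbind, fits)
fits$vstrength <- vs
fits$soma_correlation <- rr
write_table_full(fits, file.path(out_dir, "tuning_fits.csv"))

err <- orientation_diff(fits$pref_deg, fits$true_pref_deg)
cat(sprintf("tuning fits: %d spines, median |preferred-orientation error| = %.1f deg\n",
            nrow(fits), median(err)))
cat(sprintf("selectivity: median vector strength = %.2f\n", median(vs)))
cat(sprintf("spine-soma tuning correlation (QC-passed): median r = %.2f (IQR %.2f)\n",
            median(rr), IQR(rr)))
rr_all <- vapply(seq_len(dim(ds$responses)[3]), function(s) {
  m <- colMeans(subtract_bap(ds$responses[, , s], ds$dendrite)$corrected)
  tuning_correlation(m, ds$soma_tuning)
}, numeric(1))
cat(sprintf("spine-soma tuning correlation (all spines): median r = %.2f\n",
            median(rr_all, na.rm = TRUE)))
cat("note: with purely stimulus-driven synthetic trials the dendrite-\n")
cat("correlation criterion also removes strongly soma-co-tuned spines,\n")
cat("which shifts the QC-passed correlation distribution downward.\n")
cat("\nFinding: the pipeline recovers generated spine preferences after bAP\n")
cat("subtraction and QC; the synthetic cell's spine-soma correlation spread\n")
cat("can be compared directly against the model tables from\n")
cat("analysis/03_synapse_comparison.R. Real recordings exported in the same\n")
cat("tidy CSV schema (see README) flow through this script unchanged.\n")
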