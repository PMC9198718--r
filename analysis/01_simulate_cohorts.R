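#!/usr/bin/env Rscript
# Simulate the full variant panel (13 full-length constructs plus the four
# inter-CBS linker chimeras) under the study protocol and run every cell
# through the trace pipeline: P/8 leak subtraction, steady-state I-V,
# off-gating charge integration, holding-referenced Boltzmann fits and
# per-cell transport metrics. Cohort sizes follow the study's activation
# analysis where printed; variants without a printed activation n get 6
# cells. Writes per-cell and per-variant tables under results/.

suppressPackageStartupMessages(library(clc4quant))

seed <- 20260926
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

res <- run_pipeline(
  config = list(ephys = list(enabled = TRUE, variant_set = "both",
                             n_default = 6)),
  seed = seed, out_dir = out_dir)

summ <- res$summary
cat("\nPer-variant summary (activation over QC-passing cells):\n")
print(summ[, c("variant", "n", "n_qv", "v_half_mean", "v_half_sem",
               "i_ss_max_mean", "rho_mean")], digits = 3, row.names = FALSE)

nd <- summ$variant[is.na(summ$v_half_mean) | summ$n_qv < 3]
cat(sprintf(
  "\nFindings: %d variants carry too little transport current for\n",
  length(nd)),
  "activation analysis (midpoints reported ND):",
  paste(nd, collapse = ", "), "\n")
cat("Loss-of-function variants are flagged rather than contributing",
    "noise-dominated midpoints, matching how such cells are excluded in",
    "practice.\n")
cat("\nWrote per_cell_metrics.csv and variant_summary.csv to", out_dir, "\n")
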