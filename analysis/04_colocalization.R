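#!/usr/bin/env Rscript
# Colocalization analysis on synthetic two-channel image cohorts: the
# generator is calibrated by bisection on the noise-free oracle to the
# designed wild-type heterodimer overlap level (Manders R = 0.83), then a
# cohort of 11 noisy images is thresholded (Otsu) and quantified.

suppressPackageStartupMessages(library(clc4quant))

seed <- 20260926
dir.create("results", showWarnings = FALSE)

spec <- calibrate_overlap(0.83, image_synth_spec(), seed = seed)
cat(sprintf("Calibrated duplication probability: %.3f (oracle R = %.3f)\n",
            spec$overlap_prob, attr(spec, "achieved")))

rows <- do.call(rbind, lapply(1:11, function(k) {
  pair <- synth_image_pair(spec, seed = seed + k)
  res <- manders_overlap(pair, threshold_channels(pair))
  data.frame(image = k, overlap = res$overlap_coefficient, m1 = res$m1,
             m2 = res$m2, n_foreground = res$n_foreground_pixels)
}))
cat("\nPer-image Manders coefficients:\n")
print(rows, digits = 3, row.names = FALSE)
cat(sprintf("\nCohort mean R = %.3f +- %.3f s.e.m. (n = %d); designed 0.83\n",
            mean(rows$overlap), sd(rows$overlap) / sqrt(nrow(rows)),
            nrow(rows)))

write.csv(rows, "results/coloc_results.csv", row.names = FALSE)
cat("Wrote results/coloc_results.csv\n")
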