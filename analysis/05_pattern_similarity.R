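#!/usr/bin/env Rscript
# Relate pattern similarity to the similarity dimensions and training:
# cross-run Fisher-z similarity scores with the across-category baseline,
# the training main-effect model, the PC x training interaction model (the
# four-cell inversion pattern), the raw behavioral-metric model, and the
# cross-participant normative low-training alignment.

suppressMessages(library(dimshift))
ds <- readRDS("scratch/dataset.rds")
dir.create("results", showWarnings = FALSE)

write.csv(ds$scores, "results/similarity_scores.csv", row.names = FALSE)

ft <- run_analysis(ds, "fmri_training", df_method = "normal")
cat("Mean similarity score by training level: t(training) =",
    round(ft$models$full$terms$statistic[
      ft$models$full$terms$term == "training"], 2), "\n")
cat("One-sample t vs 0: low =", round(ft$one_sample$low$t, 2),
    ", high =", round(ft$one_sample$high$t, 2), "\n")

fd <- run_analysis(ds, "fmri_dimensions")
write.csv(fd$models$full$terms, "results/fmri_dimensions_terms.csv",
          row.names = FALSE)
tt <- fd$models$full$terms
cat("PC x training interactions: PC1 t =",
    round(tt$statistic[tt$term == "PC1:training"], 2), ", PC2 t =",
    round(tt$statistic[tt$term == "PC2:training"], 2), "\n")
for (lev in c("low", "high")) {
  st <- fd$subsets[[lev]]$terms
  cat(sprintf("  %s training: PC1 t = %.2f, PC2 t = %.2f\n", lev,
              st$statistic[st$term == "PC1"],
              st$statistic[st$term == "PC2"]))
}

mp <- run_analysis(ds, "memory_vs_perceptual", df_method = "normal")
write.csv(mp$models$full$terms, "results/memory_vs_perceptual_terms.csv",
          row.names = FALSE)

nm <- run_analysis(ds, "normative", df_method = "normal")
write.csv(nm$models$full$terms, "results/normative_alignment_terms.csv",
          row.names = FALSE)
cat("Normative low-training alignment slope t =",
    round(nm$models$full$terms$statistic[
      nm$models$full$terms$term == "normative_low_score"], 2), "\n")
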