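#!/usr/bin/env Rscript
# Estimate behavioral similarity matrices from the synthetic responses and
# quantify their reliability: memory confusability from post-test confusions
# and perceptual similarity from odd-one-out triplets, with the split-half
# reliability curve over participant counts.

suppressMessages(library(dimshift))
study <- readRDS("scratch/study.rds")
cfg <- study$config
dir.create("results", showWarnings = FALSE)

beach_ids <- study$stim$scene_id[study$stim$category == "beach"]
post <- study$posttest[study$posttest$category == "beach", ]

conf_group <- confusability_matrix(post, n_rounds = cfg$n_posttest_rounds,
                                   scene_ids = beach_ids,
                                   log_transform = TRUE)
write.csv(conf_group, "results/confusability_beach_log.csv")
cat("Confusability (beach): log offset eps =",
    attr(conf_group, "log_offset"), "\n")

trip <- study$triplets[study$triplets$category == "beach", ]
trip_group <- triplet_similarity_matrix(trip, scene_ids = beach_ids)
write.csv(trip_group, "results/triplet_similarity_beach.csv")
cat("Triplet similarity coverage:",
    round(100 * mean(!is.na(trip_group[upper.tri(trip_group)]))),
    "% of pairs estimated\n")

conf_p <- confusability_matrix(post, n_rounds = cfg$n_posttest_rounds,
                               scene_ids = beach_ids, aggregate = FALSE)
counts <- c(8, 16, 32, length(conf_p) %/% 2 * 2)
rc <- split_half_reliability(conf_p, counts = counts, n_permutations = 50,
                             seed = 7)
write.csv(data.frame(count = rc$counts, mean_r = rc$mean_r),
          "results/splithalf_reliability.csv", row.names = FALSE)
cat("Split-half reliability by participant count:\n")
print(round(setNames(rc$mean_r, rc$counts), 3))

dp <- compute_dprime(study$exposure)
write.csv(dp, "results/exposure_dprime.csv", row.names = FALSE)
cat("Mean exposure d' by training level:\n")
print(round(tapply(dp$dprime, dp$training_level, mean), 3))
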