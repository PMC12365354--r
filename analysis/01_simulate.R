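#!/usr/bin/env Rscript
# Simulate the default articulatory cohort (40 speakers x 5 lax vowels x
# 4-6 repetitions of 11-knot tongue contours, with coupled formants) and
# write it in the package's long landmark format.
#
# Usage: Rscript analysis/01_simulate.R [seed]

suppressPackageStartupMessages(library(tonguespace))

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L
out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- cohort_config(seed = seed)
cohort <- generate_cohort(cfg)

write.csv(contours_long(cohort$dataset), file.path(out, "contours_long.csv"),
          row.names = FALSE)
write.csv(cohort$dataset$formants, file.path(out, "formants.csv"),
          row.names = FALSE)
write.csv(cohort$truth, file.path(out, "ground_truth.csv"),
          row.names = FALSE)

cat("Simulated cohort (seed ", seed, "): ",
    length(cohort$dataset$contours), " tokens from ",
    cfg$n_speakers, " speakers.\n", sep = "")
cat("Vowel targets (theta_c in radians along the reference arc, small =",
    "anterior):\n")
print(as.data.frame(cfg$vowels))
cat("Wrote contours_long.csv, formants.csv, ground_truth.csv under ",
    out, "\n", sep = "")
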