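#!/usr/bin/env Rscript
# Extract the 16-measure battery (knot coordinates, highest point, highest
# vertex, TCP, TC, MCI) for every token of the simulated cohort.
#
# Usage: Rscript analysis/02_measures.R   (after 01_simulate.R)

suppressPackageStartupMessages(library(tonguespace))

ds <- suppressWarnings(read_contours("results/cohort/contours_long.csv",
                                     dialect = "long"))
cat("Read", length(ds$contours), "contours.\n")

measures <- measure_table(ds)
write_measures(measures, "results/measures.csv")

cat("Extracted", nrow(measures), "measure records;",
    sum(measures$degenerate), "degenerate (flat) contours.\n")
cat("Per-vowel means of two representative measures:\n")
print(aggregate(cbind(K5_X, K7_Y) ~ vowel, data = measures, mean))
cat("Wrote results/measures.csv\n")
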