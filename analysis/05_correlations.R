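#!/usr/bin/env Rscript
# Correlation structure of the 16 measures and their coupling with the
# first two formants, on within-speaker-scaled by-speaker by-item means.
#
# Usage: Rscript analysis/05_correlations.R   (after 01, 02)

suppressPackageStartupMessages(library(tonguespace))

measures <- read_measures("results/measures.csv")
formants <- read_formants("results/cohort/formants.csv")
scaled <- suppressWarnings(scale_within_speaker(measures))

mm <- speaker_item_means(scaled)
cm <- correlation_table(mm)
write.csv(round(cm$r, 6), "results/correlation_matrix.csv")

cat("Selected measure-measure correlations (by-speaker by-item means):\n")
picks <- rbind(c("K4_X", "K5_X"), c("K4_X", "K7_X"), c("K5_Y", "K7_Y"),
               c("HP_Y", "K6_Y"), c("TCP", "K5_Y"))
for (i in seq_len(nrow(picks)))
  cat(sprintf("  r(%s, %s) = %.2f\n", picks[i, 1], picks[i, 2],
              cm$r[picks[i, 1], picks[i, 2]]))

fsc <- scale_within_speaker(
  merge(formants, scaled[, c("speaker", "token", "vowel")],
        by = c("speaker", "token")),
  cols = c("f1_hz", "f2_hz"))
fm <- speaker_item_means(fsc, vars = c("f1_hz", "f2_hz"))
fc <- formant_correlations(mm, fm)
write.csv(fc$f1, "results/formant_f1.csv", row.names = FALSE)
write.csv(fc$f2, "results/formant_f2.csv", row.names = FALSE)

cat("\nMeasures ranked by |r| with F2 (top 5):\n")
print(head(as.data.frame(fc$f2), 5), digits = 3)
cat("Measures ranked by |r| with F1 (top 5):\n")
print(head(as.data.frame(fc$f1), 5), digits = 3)
cat("Wrote results/correlation_matrix.csv, formant_f1.csv, formant_f2.csv\n")
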