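#!/usr/bin/env Rscript
# Simulate the synthetic development cohort and the two cultured
# validation cell sets, and persist them for the downstream analyses.
#
# The cohort emulates the development-data structure: 5 patients sampled at
# biopsy and prostatectomy, four tissue compartments (40/30/20/10% E, E+s,
# ES, S), six pathological classes with ~21% benign cells, log-normal
# channel intensities on the 12-bit scale, and a severity gradient of the
# aberrant effect that vanishes in pure stroma. Cell counts are a
# desk-scale fraction of the full ~139k-cell database.

library(epiclass)

seed <- 20260101L
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

cfg <- default_cohort_config(cells_per_specimen = 1500, seed = seed)
cohort <- generate_cohort(cfg)
write_cell_table(cohort, "scratch/cohort.csv")

cult <- culture_cohort_config(n_normal = 2000, n_cancer = 2000, seed = seed + 1L)
culture <- rbind(as.data.frame(generate_cohort(cult$normal)),
                 as.data.frame(generate_cohort(cult$cancer)))
culture <- cell_table(culture, markers(cohort),
                      provenance = list(source = "culture_cohort_config",
                                        seed = seed + 1L))
write_cell_table(culture, "scratch/culture.csv")

summary <- as.data.frame(table(cohort$compartment, cohort$path_category))
names(summary) <- c("compartment", "path_category", "cells")
write.csv(summary, "results/cohort_summary.csv", row.names = FALSE)

cat(sprintf("simulated %d tissue cells over %d specimens (+%d culture cells)\n",
            nrow(cohort), length(unique(paste(cohort$patient_id, cohort$phase))),
            nrow(culture)))
cat(sprintf("benign share: %.1f%%; clipped at 12-bit ceiling: %d cells\n",
            100 * mean(cohort$path_category == "B"), sum(cohort$clipped)))
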