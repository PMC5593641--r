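#!/usr/bin/env Rscript
# Fuzzy-logic specimen-level diagnosis: per-cell k-NN calls are aggregated
# by the largest-share rule (the majority class fraction is read as the
# probability of that tissue diagnosis), for the tissue specimens and for
# the two cultured validation sets scored by the logistic model.

library(epiclass)

if (!file.exists("scratch/cohort.csv")) source("analysis/01_simulate.R")
lt <- log_transform(read_cell_table("scratch/cohort.csv"))
culture <- log_transform(read_cell_table("scratch/culture.csv"))
seed <- 20260101L

# tissue specimens: k-NN pathological categories, aggregated per specimen
model <- build_knn(lt, "path_category", k = 5, seed = seed)
res <- classify_cells(model, lt)
spec_id <- paste(lt$patient_id, lt$phase, sep = "_")
comps <- lapply(split(res$assigned_label, spec_id), compose)
for (nm in names(comps)) comps[[nm]]$specimen_id <- nm
classes <- sort(unique(unlist(lapply(comps, function(cp) names(cp$counts)))))
write.csv(composition_table(comps, classes),
          "results/tissue_compositions.csv", row.names = FALSE)

cat("specimen-level majority diagnoses (largest cell share = probability):\n")
for (nm in names(comps)) {
  d <- majority_diagnosis(comps[[nm]])
  cat(sprintf("  %-8s -> %-8s p=%.2f%s\n", nm, d$label, d$probability,
              if (d$tie) " (tie, severity rule)" else ""))
}

# cultured validation sets: binary logistic calls at the epithelial preset
fit <- fit_logistic(filter_compartment(lt, "E"))
probs <- predict_prob(fit, culture, cutoff = 0.75)
cult_comp <- lapply(split(probs$predicted_label, culture$patient_id),
                    function(l) compose(l, class_order = c("normal", "aberrant")))
for (nm in names(cult_comp)) cult_comp[[nm]]$specimen_id <- nm
write.csv(composition_table(cult_comp, c("normal", "aberrant")),
          "results/culture_compositions.csv", row.names = FALSE)
cat("\ncultured validation sets (logistic calls at cutoff 0.75):\n")
for (nm in names(cult_comp)) {
  cp <- cult_comp[[nm]]
  cat(sprintf("  %-8s -> %5.1f%% normal / %5.1f%% aberrant\n", nm,
              100 * cp$fractions["normal"], 100 * cp$fractions["aberrant"]))
}
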