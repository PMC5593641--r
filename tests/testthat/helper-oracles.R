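# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths.

# moment-based sample skewness
sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2)^1.5)
}

# O(n^2) pairwise-concordance AUC with ties counted 1/2
brute_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Exhaustive-distance k-NN via stats::mahalanobis, plurality vote,
# distance ties by reference index, plurality ties -> ABSTAIN.
brute_knn <- function(query, ref, ref_labels, cov_inv, k) {
  apply(query, 1, function(q) {
    d <- sqrt(stats::mahalanobis(ref, center = q, cov = cov_inv,
                                 inverted = TRUE))
    nb <- order(d)[seq_len(k)]
    tl <- table(ref_labels[nb])
    winners <- names(tl)[tl == max(tl)]
    if (length(winners) == 1) winners else "ABSTAIN"
  })
}

# brute-force confusion counts at one probability cutoff
brute_confusion <- function(probs, truth, cutoff) {
  pred <- probs >= cutoff
  c(tp = sum(pred & truth == 1), fn = sum(!pred & truth == 1),
    tn = sum(!pred & truth == 0), fp = sum(pred & truth == 0))
}

# minimal hand-built cell table: n cells, given markers matrix
make_table <- function(intensities, compartment = "E", path_category = "B",
                       gleason_group = "B", patient_id = "P1",
                       phase = "biopsy1", log_scale = FALSE) {
  intensities <- as.matrix(intensities)
  n <- nrow(intensities)
  df <- data.frame(
    cell_id = sprintf("c%05d", seq_len(n)),
    patient_id = rep_len(patient_id, n),
    phase = rep_len(phase, n),
    frame_id = "f1",
    compartment = rep_len(compartment, n),
    path_category = rep_len(path_category, n),
    gleason_group = rep_len(gleason_group, n),
    stringsAsFactors = FALSE
  )
  df <- cbind(df, as.data.frame(intensities, check.names = FALSE))
  prov <- if (log_scale) list(log_transformed = TRUE) else list()
  cell_table(df, colnames(intensities), provenance = prov)
}

# natural-log odds-ratio truth of the published epithelial model
# (intercept first), used for parameter-recovery simulations
epithelial_truth_beta <- function() {
  rep <- ref_logistic_reports()$epithelial
  or <- rep$odds_ratio[match(c("(Intercept)", "lnDAPI", "lnAMACR", "ln5mC",
                               "ln5hmC"), rep$term)]
  log(or)
}
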