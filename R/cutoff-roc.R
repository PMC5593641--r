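#' Sensitivity/specificity scan over probability cutoffs
#'
#' Classification tables for every probability cutoff from 0 to 1 in
#' increments of 0.05 (21 rows): a cell is called aberrant when its
#' estimated cancer probability is at least the cutoff. Sensitivity is the
#' fraction of truly aberrant cells called aberrant, specificity the
#' fraction of truly normal cells called normal, and `percent_correct`
#' `(TP + TN) / N`. The chosen operating cutoff balances the two;
#' [select_cutoff()] maximizes the Youden index
#' `sensitivity + specificity - 1`, ties resolved toward the smallest
#' cutoff.
#'
#' @param probs Numeric cancer probabilities (or the tibble from
#'   [predict_prob()]).
#' @param truth Integer 0/1 vector (1 = aberrant), both classes present.
#' @return A `cutoff_scan` tibble: `cutoff`, `sensitivity`, `specificity`,
#'   `percent_correct` (21 rows).
#' @export
cutoff_scan <- function(probs, truth) {
  probs <- scores_from(probs)
  truth <- as.integer(truth)
  stopifnot(length(probs) == length(truth))
  if (length(unique(truth)) < 2) {
    stop("truth is single-class; cannot form sensitivity and specificity",
         call. = FALSE)
  }
  cutoffs <- seq(0, 1, by = 0.05)
  n_pos <- sum(truth == 1)
  n_neg <- sum(truth == 0)
  rows <- lapply(cutoffs, function(ct) {
    pred <- probs >= ct
    tp <- sum(pred & truth == 1)
    tn <- sum(!pred & truth == 0)
    tibble::tibble(cutoff = ct,
                   sensitivity = tp / n_pos,
                   specificity = tn / n_neg,
                   percent_correct = 100 * (tp + tn) / length(truth))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cutoff_scan", class(out))
  out
}

#' @rdname cutoff_scan
#' @param scan A `cutoff_scan`.
#' @export
select_cutoff <- function(scan) {
  stopifnot(inherits(scan, "cutoff_scan"))
  youden <- scan$sensitivity + scan$specificity - 1
  scan$cutoff[which.max(youden)]   # which.max takes the first (smallest) tie
}

scores_from <- function(probs) {
  if (is.data.frame(probs)) {
    stopifnot("prob_cancer" %in% names(probs))
    probs <- probs$prob_cancer
  }
  as.numeric(probs)
}

#' ROC curve and Mann-Whitney AUC
#'
#' The receiver operating characteristic over all distinct score
#' thresholds, and the area under it computed as the Mann-Whitney
#' concordance probability: the probability that a random aberrant cell
#' scores above a random normal cell, with tied scores counted 1/2. The
#' curve starts at (0,0), ends at (1,1), and the AUC is invariant under
#' any strictly increasing transform of the scores.
#'
#' @inheritParams cutoff_scan
#' @return A `roc_curve`: tibble of (`fpr`, `tpr`) points with an `auc`
#'   attribute (also returned by `auc()`).
#' @export
roc_auc <- function(probs, truth) {
  probs <- scores_from(probs)
  truth <- as.integer(truth)
  stopifnot(length(probs) == length(truth))
  if (length(unique(truth)) < 2) {
    stop("truth is single-class; ROC undefined", call. = FALSE)
  }
  n_pos <- sum(truth == 1)
  n_neg <- sum(truth == 0)
  # rank-based Mann-Whitney with midranks for ties
  r <- rank(probs, ties.method = "average")
  auc <- (sum(r[truth == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(probs), decreasing = TRUE)
  ord <- order(probs, decreasing = TRUE)
  tp <- cumsum(truth[ord] == 1)
  fp <- cumsum(truth[ord] == 0)
  keep <- !duplicated(probs[ord], fromLast = TRUE)  # last index per threshold
  curve <- tibble::tibble(
    fpr = c(0, fp[keep] / n_neg),
    tpr = c(0, tp[keep] / n_pos)
  )
  structure(curve, auc = auc, class = c("roc_curve", class(curve)))
}

#' @rdname roc_auc
#' @param roc A `roc_curve`.
#' @export
auc <- function(roc) attr(roc, "auc")

#' Qualitative discrimination band for an AUC
#'
#' Hosmer-Lemeshow interpretation rules: 0.5 means no discrimination (the
#' model is no better than a coin flip), above 0.7 up to 0.8 acceptable,
#' above 0.8 up to 0.9 excellent, above 0.9 outstanding. The band for
#' (0.5, 0.7] is not covered by those rules and is labeled `"poor"` here
#' as a documented extension; values below 0.5 are `"worse-than-chance"`.
#'
#' @param auc A number in \[0, 1\].
#' @return One of `"none"`, `"poor"`, `"acceptable"`, `"excellent"`,
#'   `"outstanding"`, `"worse-than-chance"`.
#' @export
discrimination_band <- function(auc) {
  if (!is.numeric(auc) || length(auc) != 1 || is.na(auc) || auc < 0 || auc > 1) {
    stop("auc must be a single number in [0, 1]", call. = FALSE)
  }
  if (auc < 0.5) return("worse-than-chance")
  if (auc == 0.5) return("none")
  if (auc <= 0.7) return("poor")
  if (auc <= 0.8) return("acceptable")
  if (auc <= 0.9) return("excellent")
  "outstanding"
}
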