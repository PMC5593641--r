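#' Fuzzy-logic specimen-level composition from per-cell labels
#'
#' Cell-level calls are aggregated into a specimen-level probabilistic
#' diagnosis by the largest-share rule: the fraction of classified cells
#' in each class is read as the probability of that tissue-level
#' diagnosis, so a specimen with 80% normal cells has an 80% probability
#' of being normal tissue and a 20% probability of malignancy. Abstained
#' cells are excluded from the denominator but always reported.
#'
#' @param labels Character vector of per-cell class labels for one
#'   specimen (`"ABSTAIN"` entries are counted separately).
#' @param specimen_id Identifier carried into the result.
#' @param class_order Optional class vocabulary fixing count ordering
#'   (defaults to the sorted observed labels).
#' @return A `tissue_composition`: `specimen_id`, `counts` (named integer),
#'   `fractions`, `majority_label`, `majority_fraction`, `n_cells`,
#'   `n_abstained`, `status` (`"ok"` or `"indeterminate"` when no cell was
#'   classified).
#' @export
compose <- function(labels, specimen_id = "specimen", class_order = NULL) {
  if (length(labels) == 0) stop("at least one cell required", call. = FALSE)
  abst <- labels == "ABSTAIN"
  cl <- labels[!abst]
  if (is.null(class_order)) class_order <- sort(unique(cl))
  counts <- table(factor(cl, levels = class_order))
  counts <- stats::setNames(as.integer(counts), names(counts))
  if (length(cl) == 0) {
    return(structure(list(specimen_id = specimen_id, counts = counts,
                          fractions = counts * NA_real_,
                          majority_label = NA_character_,
                          majority_fraction = NA_real_,
                          n_cells = length(labels),
                          n_abstained = sum(abst),
                          status = "indeterminate"),
                     class = "tissue_composition"))
  }
  fractions <- counts / sum(counts)
  top <- which.max(fractions)
  structure(list(specimen_id = specimen_id, counts = counts,
                 fractions = fractions,
                 majority_label = names(fractions)[top],
                 majority_fraction = unname(fractions[top]),
                 n_cells = length(labels), n_abstained = sum(abst),
                 status = "ok"),
            class = "tissue_composition")
}

#' @export
print.tissue_composition <- function(x, ...) {
  cat(sprintf("<tissue_composition> %s: %d cells (%d abstained)\n",
              x$specimen_id, x$n_cells, x$n_abstained))
  if (x$status == "indeterminate") {
    cat("  indeterminate: no classified cells\n")
  } else {
    cat(sprintf("  majority %s at %.2f%%\n", x$majority_label,
                100 * x$majority_fraction))
    print(round(100 * x$fractions, 2))
  }
  invisible(x)
}

#' Formatted composition report (counts + percentage rows)
#'
#' Renders one or more specimen compositions as the conventional
#' two-row-per-specimen layout: a row of class counts with a `Total`
#' column, and beneath it a percentage row rounded half-away-from-zero to
#' two decimals (the `Total` percentage displays as 100). Raw fractions
#' remain available at full precision in the `tissue_composition` objects;
#' rounding here is display-only.
#'
#' @param compositions A `tissue_composition` or list of them.
#' @param class_order Character vector fixing the class column order; must
#'   cover every observed class.
#' @return A data frame: `specimen_id`, `row` (`"count"`/`"percent"`), one
#'   column per class, `Total`.
#' @export
composition_table <- function(compositions, class_order) {
  if (inherits(compositions, "tissue_composition")) {
    compositions <- list(compositions)
  }
  rows <- lapply(compositions, function(cp) {
    stopifnot(inherits(cp, "tissue_composition"))
    unknown <- setdiff(names(cp$counts), class_order)
    if (length(unknown) > 0) {
      stop("class(es) outside class_order: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cnt <- stats::setNames(rep(0L, length(class_order)), class_order)
    cnt[names(cp$counts)] <- cp$counts
    total <- sum(cnt)
    pct <- if (total > 0) round_half_away(100 * cnt / total, 2) else cnt * NA_real_
    count_row <- data.frame(specimen_id = cp$specimen_id, row = "count",
                            t(cnt), Total = total, check.names = FALSE)
    pct_row <- data.frame(specimen_id = cp$specimen_id, row = "percent",
                          t(pct), Total = 100, check.names = FALSE)
    rbind(count_row, pct_row)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Majority (largest-share) tissue diagnosis
#'
#' The specimen-level diagnosis is the class holding the largest share of
#' classified cells, reported with that share as its probability. An exact
#' tie is resolved toward the more severe class under the documented
#' severity orders ([path_severity], [gleason_severity]) — conservative
#' toward malignancy — and flagged.
#'
#' @param composition A `tissue_composition`.
#' @param severity_order Class ranking from least to most severe used for
#'   tie-breaking; classes absent from it rank lowest.
#' @return A list: `label`, `probability`, `tie` (logical), `status`.
#' @export
majority_diagnosis <- function(composition, severity_order = path_severity) {
  stopifnot(inherits(composition, "tissue_composition"))
  if (composition$status == "indeterminate") {
    return(list(label = NA_character_, probability = NA_real_, tie = FALSE,
                status = "indeterminate"))
  }
  fr <- composition$fractions
  top <- max(fr)
  winners <- names(fr)[fr == top]
  tie <- length(winners) > 1
  if (tie) {
    sev <- match(winners, severity_order)
    sev[is.na(sev)] <- 0
    winners <- winners[which.max(sev)]
  }
  list(label = winners, probability = unname(top), tie = tie, status = "ok")
}
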