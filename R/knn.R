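#' Build a Mahalanobis k-nearest-neighbor classifier
#'
#' Polychotomous cell classifier: a query cell takes the plurality label
#' of its `k` closest reference cells under Mahalanobis distance, the
#' metric defined by the inverse pooled covariance of the reference
#' log-intensities (so the scale of distance is the standard deviation of
#' the data, not raw intensity units). To keep the reference portable the
#' development cells are capped at `subsample_size` (default 30,000),
#' drawn proportionally by class (largest-remainder allocation) with a
#' fixed seed.
#'
#' @param table A log-transformed [cell_table()].
#' @param label_scheme `"path_category"` or `"gleason_group"`.
#' @param k Neighbor count (default 5).
#' @param subsample_size Reference cap (default 30,000).
#' @param stratify Draw the subsample proportionally by class.
#' @param seed Subsampling seed.
#' @param markers Marker columns to use.
#' @return A `knn_model`: `reference` (matrix), `labels`, `cov_inv`,
#'   `whitener` (Cholesky factor of `cov_inv`), `k`, `label_scheme`,
#'   `markers`, `seed`.
#' @export
build_knn <- function(table, label_scheme = c("path_category", "gleason_group"),
                      k = 5L, subsample_size = 30000L, stratify = TRUE,
                      seed = 1L, markers = NULL) {
  stopifnot(inherits(table, "cell_table"), k >= 1)
  label_scheme <- match.arg(label_scheme)
  if (is.null(markers)) markers <- attr(table, "markers")
  if (length(markers) < 2) stop("need at least 2 markers", call. = FALSE)
  labels <- table[[label_scheme]]
  x <- as.matrix(as.data.frame(table, check.names = FALSE)[, markers, drop = FALSE])

  idx <- seq_len(nrow(x))
  if (nrow(x) > subsample_size) {
    idx <- with_seed(seed, {
      if (stratify) {
        cls <- sort(unique(labels))
        sizes <- vapply(cls, function(cl) sum(labels == cl), integer(1))
        alloc <- largest_remainder(subsample_size, sizes)
        unlist(lapply(seq_along(cls), function(i) {
          pool <- which(labels == cls[i])
          sort(sample(pool, alloc[i]))
        }), use.names = FALSE)
      } else {
        sort(sample(idx, subsample_size))
      }
    })
  }
  ref <- x[idx, , drop = FALSE]
  ref_labels <- labels[idx]
  tab <- table(ref_labels)
  if (any(tab < k)) {
    stop("class(es) with fewer than k reference cells: ",
         paste(names(tab)[tab < k], collapse = ", "), call. = FALSE)
  }
  sigma <- stats::cov(ref)
  cov_inv <- tryCatch(solve(sigma), error = function(e) {
    stop("singular pooled covariance; jitter the data or drop a marker",
         call. = FALSE)
  })
  structure(list(reference = ref, labels = ref_labels,
                 cov_inv = cov_inv, whitener = chol(cov_inv),
                 k = as.integer(k), label_scheme = label_scheme,
                 markers = markers, seed = seed,
                 subsample_size = subsample_size),
            class = "knn_model")
}

#' @export
print.knn_model <- function(x, ...) {
  cat(sprintf("<knn_model> k=%d, %d reference cells, scheme=%s\n",
              x$k, nrow(x$reference), x$label_scheme))
  print(table(x$labels))
  invisible(x)
}

#' Mahalanobis distance between two marker vectors
#'
#' `d = sqrt((x0 - xr)' S^{-1} (x0 - xr))` for a supplied inverse
#' covariance `S^{-1}`; reduces to Euclidean distance when `S^{-1}` is the
#' identity, and equals Euclidean distance after whitening both points by
#' the Cholesky factor of `S^{-1}`.
#'
#' @param x0,xr Numeric vectors of equal length.
#' @param cov_inv Inverse covariance matrix (symmetric positive definite).
#' @return Nonnegative distance.
#' @export
mahalanobis_distance <- function(x0, xr, cov_inv) {
  if (length(x0) != length(xr) || length(x0) != nrow(cov_inv)) {
    stop("dimension mismatch", call. = FALSE)
  }
  d <- x0 - xr
  sqrt(drop(t(d) %*% cov_inv %*% d))
}

#' Classify cells against a k-NN reference
#'
#' For every query cell the `k` reference cells with smallest Mahalanobis
#' distance are found by exhaustive scan (distance ties broken by
#' reference order), and the plurality label among them is assigned. A
#' tie in the plurality vote yields `ABSTAIN` — the model declines to
#' classify the cell rather than guessing.
#'
#' @param model A `knn_model`.
#' @param table A log-transformed [cell_table()] with the model's markers.
#' @param chunk_size Queries processed per block (memory/speed trade-off).
#' @return A `knn_result` tibble: `cell_id`, `assigned_label` (or
#'   `"ABSTAIN"`), `top_count`, `mean_distance`, plus one `n_<label>`
#'   neighbor-count column per reference class.
#' @export
classify_cells <- function(model, table, chunk_size = 2000L) {
  stopifnot(inherits(model, "knn_model"), inherits(table, "cell_table"))
  if (nrow(table) == 0) stop("empty input table", call. = FALSE)
  if (!all(model$markers %in% attr(table, "markers"))) {
    stop("table does not carry the model's marker set", call. = FALSE)
  }
  x <- as.matrix(as.data.frame(table, check.names = FALSE)[, model$markers,
                                                           drop = FALSE])
  U <- model$whitener
  refw <- model$reference %*% t(U)
  qw <- x %*% t(U)
  ref_norm <- rowSums(refw^2)
  k <- model$k
  classes <- sort(unique(model$labels))
  n <- nrow(qw)
  assigned <- character(n)
  top_count <- integer(n)
  mean_dist <- numeric(n)
  counts <- matrix(0L, n, length(classes), dimnames = list(NULL, classes))
  for (start in seq(1, n, by = chunk_size)) {
    rows <- start:min(start + chunk_size - 1, n)
    qb <- qw[rows, , drop = FALSE]
    # squared Euclidean distances in whitened space = squared Mahalanobis
    d2 <- outer(rowSums(qb^2), ref_norm, "+") - 2 * qb %*% t(refw)
    d2[d2 < 0] <- 0
    for (i in seq_along(rows)) {
      nb <- order(d2[i, ])[seq_len(k)]       # stable: ties by reference index
      lab <- model$labels[nb]
      tl <- table(lab)
      best <- max(tl)
      winners <- names(tl)[tl == best]
      r <- rows[i]
      assigned[r] <- if (length(winners) == 1) winners else "ABSTAIN"
      top_count[r] <- best
      mean_dist[r] <- mean(sqrt(d2[i, nb]))
      counts[r, names(tl)] <- as.integer(tl)
    }
  }
  out <- tibble::tibble(cell_id = table$cell_id, assigned_label = assigned,
                        top_count = top_count, mean_distance = mean_dist)
  cn <- paste0("n_", classes)
  for (j in seq_along(classes)) out[[cn[j]]] <- unname(counts[, j])
  class(out) <- c("knn_result", class(out))
  out
}

#' Confusion matrix, per-class recall, accuracy and abstain rate
#'
#' Evaluation summary for a k-NN classification against known labels.
#' Accuracy and the confusion matrix are computed over classified
#' (non-abstained) cells only; the abstain rate is reported separately,
#' mirroring the convention of quoting accuracy on the classifiable
#' portion of cells.
#'
#' @param result A `knn_result`.
#' @param truth Character vector of true labels, aligned with `result`.
#' @return A list: `confusion` (row-normalized, rows = truth),
#'   `confusion_counts`, `per_class_recall`, `accuracy` (NA with
#'   `all_abstained = TRUE` if nothing was classified), `abstain_rate`.
#' @export
knn_accuracy_heatmap <- function(result, truth) {
  stopifnot(inherits(result, "knn_result"), length(truth) == nrow(result))
  classified <- result$assigned_label != "ABSTAIN"
  abstain_rate <- mean(!classified)
  if (!any(classified)) {
    return(list(confusion = NULL, confusion_counts = NULL,
                per_class_recall = NULL, accuracy = NA_real_,
                abstain_rate = 1, all_abstained = TRUE))
  }
  tr <- truth[classified]
  pr <- result$assigned_label[classified]
  lv <- sort(unique(c(tr, pr)))
  cm <- table(factor(tr, levels = lv), factor(pr, levels = lv))
  cm_norm <- sweep(cm, 1, pmax(rowSums(cm), 1), "/")
  list(confusion = cm_norm, confusion_counts = cm,
       per_class_recall = diag(cm) / pmax(rowSums(cm), 1),
       accuracy = mean(tr == pr), abstain_rate = abstain_rate,
       all_abstained = FALSE)
}
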