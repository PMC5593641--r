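#' Principal component analysis of a marker panel
#'
#' Eigendecomposition of the sample correlation matrix (default) or
#' covariance matrix of the log-intensity columns: each component `y_i` is
#' the linear combination `a_i1 x_1 + ... + a_ip x_p` of the (centered,
#' optionally scaled) markers, components ordered by decreasing explained
#' variance. Channels sit on different intensity scales, so
#' correlation-matrix PCA (`standardize = TRUE`) is the default. The sign
#' of each component is fixed by making its largest-magnitude loading
#' positive, so results are deterministic across runs.
#'
#' @param table A log-transformed [cell_table()].
#' @param markers Marker columns to use (default: all of them).
#' @param standardize Scale each marker to unit variance before
#'   decomposition (correlation-matrix PCA).
#' @return A `pca_fit` with elements `loadings` (rows = components,
#'   columns = markers, orthonormal), `eigenvalues` (nonincreasing),
#'   `scores` (per-cell component coordinates), `center`, `scale`,
#'   `markers`.
#' @export
fit_pca <- function(table, markers = NULL, standardize = TRUE) {
  stopifnot(inherits(table, "cell_table"))
  if (is.null(markers)) markers <- attr(table, "markers")
  if (length(markers) < 2) stop("need at least 2 markers", call. = FALSE)
  if (nrow(table) < 3) stop("need at least 3 cells", call. = FALSE)
  x <- as.matrix(as.data.frame(table, check.names = FALSE)[, markers, drop = FALSE])
  ctr <- colMeans(x)
  scl <- if (standardize) apply(x, 2, stats::sd) else rep(1, ncol(x))
  if (any(scl == 0)) {
    stop("constant marker column(s): ",
         paste(markers[scl == 0], collapse = ", "), call. = FALSE)
  }
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  S <- stats::cov(xs)
  ed <- eigen(S, symmetric = TRUE)
  vals <- pmax(ed$values, 0)
  A <- t(ed$vectors)                        # rows = components
  # deterministic sign: largest |loading| per component made positive
  for (i in seq_len(nrow(A))) {
    j <- which.max(abs(A[i, ]))
    if (A[i, j] < 0) A[i, ] <- -A[i, ]
  }
  dimnames(A) <- list(paste0("PC", seq_len(nrow(A))), markers)
  scores <- xs %*% t(A)
  colnames(scores) <- rownames(A)
  structure(list(loadings = A, eigenvalues = vals, scores = scores,
                 center = ctr, scale = scl, markers = markers,
                 standardize = standardize),
            class = "pca_fit")
}

#' @export
print.pca_fit <- function(x, ...) {
  cat(sprintf("<pca_fit> %d components over (%s)\n", length(x$eigenvalues),
              paste(x$markers, collapse = ", ")))
  pct <- 100 * x$eigenvalues / sum(x$eigenvalues)
  cat("  variance explained (%):", paste(sprintf("%.1f", pct), collapse = ", "),
      "\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Project cells onto fitted principal components
#'
#' Applies the stored centering/scaling and loading matrix to a table with
#' the same marker set; projecting the training table reproduces the
#' stored scores, and a cell at the training mean maps to the origin.
#'
#' @param fit A `pca_fit` from [fit_pca()].
#' @param table A [cell_table()] with the fit's markers.
#' @param n_components Number of leading components to return.
#' @return Numeric matrix of scores (cells x components).
#' @export
pca_project <- function(fit, table, n_components = length(fit$markers)) {
  stopifnot(inherits(fit, "pca_fit"), inherits(table, "cell_table"))
  if (!all(fit$markers %in% attr(table, "markers"))) {
    stop("table does not carry the fitted marker set", call. = FALSE)
  }
  x <- as.matrix(as.data.frame(table, check.names = FALSE)[, fit$markers, drop = FALSE])
  xs <- sweep(sweep(x, 2, fit$center), 2, fit$scale, "/")
  sc <- xs %*% t(fit$loadings[seq_len(n_components), , drop = FALSE])
  colnames(sc) <- rownames(fit$loadings)[seq_len(n_components)]
  sc
}

#' Stratified PCA with tidy PC1/PC2 scatter export
#'
#' Fits one PCA per stratum (tissue compartment, pathological category or
#' Gleason group) and returns, alongside the per-stratum fits, a tidy
#' table of PC1/PC2 coordinates per cell suitable for scatter plotting —
#' the workflow behind the compartment-wise exploration where the
#' epithelial compartment segregates diagnosis classes best while the pure
#' stroma shows no class covariation. Strata with fewer than 3 cells are
#' skipped with a warning.
#'
#' @param table A log-transformed [cell_table()].
#' @param stratum_key One of `"compartment"`, `"path_category"`,
#'   `"gleason_group"`.
#' @param markers,standardize Passed to [fit_pca()].
#' @return A list with `fits` (named list of `pca_fit`) and `scatter`
#'   (tibble: `cell_id`, `stratum`, `PC1`, `PC2`, `path_category`,
#'   `gleason_group`).
#' @export
stratified_pca_report <- function(table,
                                  stratum_key = c("compartment",
                                                  "path_category",
                                                  "gleason_group"),
                                  markers = NULL, standardize = TRUE) {
  stopifnot(inherits(table, "cell_table"))
  stratum_key <- match.arg(stratum_key)
  strata <- unique(table[[stratum_key]])
  strata <- strata[!is.na(strata)]
  fits <- list()
  rows <- list()
  for (s in strata) {
    sub <- rebuild(table[!is.na(table[[stratum_key]]) &
                           table[[stratum_key]] == s, , drop = FALSE], table)
    if (nrow(sub) < 3) {
      warning("stratum '", s, "' has fewer than 3 cells; skipped",
              call. = FALSE)
      next
    }
    f <- fit_pca(sub, markers = markers, standardize = standardize)
    fits[[s]] <- f
    rows[[s]] <- tibble::tibble(
      cell_id = sub$cell_id,
      stratum = s,
      PC1 = f$scores[, 1],
      PC2 = f$scores[, 2],
      path_category = sub$path_category,
      gleason_group = sub$gleason_group
    )
  }
  list(fits = fits, scatter = do.call(rbind, rows))
}

#' Between-class centroid separation on PC1
#'
#' Summary used to compare strata: the absolute difference between class
#' centroids of the PC1 score, for a binary labeling of cells.
#'
#' @param fit A `pca_fit`.
#' @param labels Logical or two-level vector aligned with the fitted cells.
#' @return Absolute centroid difference on PC1 (score units).
#' @export
pc1_separation <- function(fit, labels) {
  stopifnot(inherits(fit, "pca_fit"))
  f <- factor(labels)
  if (nlevels(f) != 2) stop("labels must have exactly two levels", call. = FALSE)
  m <- tapply(fit$scores[, 1], f, mean)
  abs(diff(m))
}
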