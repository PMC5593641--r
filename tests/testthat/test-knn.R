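two_class_table <- function(n_per = 250, sep = 2, p = 3, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p), ncol = p),
             matrix(rnorm(n_per * p, mean = sep), ncol = p))
  colnames(x) <- paste0("m", seq_len(p))
  make_table(x, log_scale = TRUE,
             path_category = rep(c("B", "AC"), each = n_per))
}

test_that("mahalanobis_distance satisfies the closed forms and metric axioms", {
  expect_equal(mahalanobis_distance(c(1, 2), c(4, 6), diag(2)), 5)  # Euclidean
  expect_equal(mahalanobis_distance(c(3, 3), c(3, 3), diag(2)), 0)
  # covariance [[4,0],[0,1]], difference (2,1): d = sqrt(4/4 + 1/1) = sqrt(2)
  expect_equal(mahalanobis_distance(c(2, 1), c(0, 0),
                                    solve(matrix(c(4, 0, 0, 1), 2))),
               sqrt(2))
  expect_error(mahalanobis_distance(1:3, 1:2, diag(2)), "dimension")
  set.seed(4)
  S <- crossprod(matrix(rnorm(9), 3))
  Sinv <- solve(S)
  for (i in 1:20) {
    a <- rnorm(3); b <- rnorm(3)
    expect_gte(mahalanobis_distance(a, b, Sinv), 0)
    expect_equal(mahalanobis_distance(a, b, Sinv),
                 mahalanobis_distance(b, a, Sinv))
  }
  a <- rnorm(3)
  expect_equal(mahalanobis_distance(a, a, Sinv), 0)
})

test_that("mahalanobis k-NN equals Euclidean k-NN after whitening", {
  set.seed(21)
  S <- crossprod(matrix(rnorm(16), 4)) + diag(4)
  Sinv <- solve(S)
  U <- chol(Sinv)
  for (i in 1:100) {
    a <- rnorm(4); b <- rnorm(4)
    d_m <- mahalanobis_distance(a, b, Sinv)
    d_e <- sqrt(sum((U %*% a - U %*% b)^2))
    expect_lt(abs(d_m - d_e), 1e-10)
  }
})

test_that("small tables become the reference wholesale; subsampling is seeded", {
  tab <- two_class_table(100)
  m <- build_knn(tab, "path_category", k = 5, subsample_size = 30000, seed = 3)
  expect_identical(nrow(m$reference), 200L)
  m1 <- build_knn(tab, "path_category", subsample_size = 120, seed = 3)
  m2 <- build_knn(tab, "path_category", subsample_size = 120, seed = 3)
  expect_identical(m1$reference, m2$reference)
  expect_identical(m1$labels, m2$labels)
  m3 <- build_knn(tab, "path_category", subsample_size = 120, seed = 4)
  expect_false(identical(m3$reference, m1$reference))
})

test_that("a full-scale cohort is capped at 30,000 proportionally by class", {
  counts <- c(rep(13916L, 9), 13921L)   # 139,165 cells over ten specimens
  specimens <- data.frame(
    specimen_id = paste0("S", 1:10),
    patient_id = rep(paste0("P", 1:5), each = 2),
    phase = rep(c("biopsy1", "prostatectomy"), 5),
    cells = counts
  )
  cfg <- cohort_config(specimens, epiclass:::gradient_profiles(), seed = 19)
  tab <- log_transform(generate_cohort(cfg))
  expect_identical(nrow(tab), 139165L)
  m <- build_knn(tab, "path_category", subsample_size = 30000, seed = 5)
  expect_identical(nrow(m$reference), 30000L)
  expected <- 30000 * table(tab$path_category) / nrow(tab)
  observed <- table(m$labels)
  expect_true(all(abs(observed - expected[names(observed)]) <= 1))
})

test_that("each reference cell is its own nearest neighbor at k = 1", {
  tab <- two_class_table(50, seed = 6)
  m <- build_knn(tab, "path_category", k = 1)
  res <- classify_cells(m, tab)
  expect_identical(res$assigned_label, tab$path_category)
  expect_true(all(res$assigned_label != "ABSTAIN"))   # abstention impossible
  # self-distances are zero up to cross-product cancellation error
  expect_true(all(res$mean_distance < 1e-5))
})

test_that("a tied plurality vote abstains", {
  x <- rbind(c(-1, 0.1), c(-20, -0.2), c(1, -0.1), c(20, 0.2))
  colnames(x) <- c("m1", "m2")
  ref <- make_table(x, log_scale = TRUE,
                    path_category = c("B", "B", "AC", "AC"))
  m <- build_knn(ref, "path_category", k = 2)
  query <- make_table(matrix(c(0, 0), 1, dimnames = list(NULL, c("m1", "m2"))),
                      log_scale = TRUE)
  res <- classify_cells(m, query)
  expect_identical(res$assigned_label, "ABSTAIN")
  expect_identical(res$n_AC + res$n_B, 2L)   # neighbor counts sum to k
})

test_that("classification matches the exhaustive brute-force oracle", {
  set.seed(31)
  p <- 4
  ref_x <- matrix(rnorm(2000 * p), ncol = p)
  ref_x[1001:2000, ] <- ref_x[1001:2000, ] + 1.2
  colnames(ref_x) <- paste0("m", 1:p)
  ref <- make_table(ref_x, log_scale = TRUE,
                    path_category = rep(c("B", "AC"), each = 1000))
  qx <- matrix(rnorm(500 * p, 0.6), ncol = p)
  colnames(qx) <- colnames(ref_x)
  query <- make_table(qx, log_scale = TRUE)
  m <- build_knn(ref, "path_category", k = 5)
  res <- classify_cells(m, query, chunk_size = 123)   # cross chunk borders
  oracle <- brute_knn(qx, ref_x, ref$path_category, m$cov_inv, k = 5)
  expect_identical(res$assigned_label, unname(oracle))
  counts <- res$n_AC + res$n_B
  expect_true(all(counts == 5L))
})

test_that("evaluation summarizes confusion, recall, accuracy and abstention", {
  tab <- two_class_table(200, sep = 6, seed = 12)   # far apart: near-perfect
  m <- build_knn(tab, "path_category", k = 5)
  res <- classify_cells(m, tab)
  ev <- knn_accuracy_heatmap(res, tab$path_category)
  expect_equal(ev$accuracy, 1)
  expect_equal(unname(diag(as.matrix(ev$confusion))), c(1, 1))
  expect_equal(ev$abstain_rate, 0)

  all_abst <- res
  all_abst$assigned_label <- rep("ABSTAIN", nrow(res))
  ev2 <- knn_accuracy_heatmap(all_abst, tab$path_category)
  expect_true(ev2$all_abstained)
  expect_identical(ev2$abstain_rate, 1)
  expect_true(is.na(ev2$accuracy))
  expect_error(knn_accuracy_heatmap(res, tab$path_category[1:10]), "length")
})

test_that("true labels beat permuted labels on a separated 6-class cohort", {
  cfg <- default_cohort_config(cells_per_specimen = 600, seed = 23,
                               effect_scale = 3)
  lt <- filter_compartment(log_transform(generate_cohort(cfg)), "E")
  m <- build_knn(lt, "path_category", k = 5, seed = 2)
  res <- classify_cells(m, lt)
  ev <- knn_accuracy_heatmap(res, lt$path_category)
  set.seed(99)
  ev_perm <- knn_accuracy_heatmap(res, sample(lt$path_category))
  expect_gt(ev$accuracy, ev_perm$accuracy)
})

test_that("degenerate k-NN inputs are rejected", {
  tab <- two_class_table(30, seed = 2)
  expect_error(build_knn(tab, "path_category", k = 40), "fewer than k")
  const <- make_table(cbind(m1 = rep(1, 20), m2 = rep(2, 20)),
                      log_scale = TRUE,
                      path_category = rep(c("B", "AC"), 10))
  expect_error(build_knn(const, "path_category", k = 2), "singular")
  m <- build_knn(tab, "path_category", k = 3)
  expect_error(classify_cells(m, tab[0, ]), "empty|cell_table")
})
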