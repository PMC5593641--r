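single_profile_config <- function(n, seed = 1, log_mean = NULL, log_cov = NULL) {
  if (is.null(log_mean)) log_mean <- c(DAPI = 6.0, AMACR = 5.2, `5mC` = 6.0,
                                       `5hmC` = 5.8)
  if (is.null(log_cov)) {
    log_cov <- diag(c(0.16, 0.25, 0.2, 0.2))
    dimnames(log_cov) <- list(names(log_mean), names(log_mean))
  }
  cohort_config(
    specimens = data.frame(specimen_id = "S1", patient_id = "P1",
                           phase = "biopsy1", cells = n),
    profiles = list(class_profile("B", "B", "E", log_mean, log_cov, 1)),
    seed = seed
  )
}

test_that("generation is byte-identical under a fixed seed", {
  cfg <- default_cohort_config(cells_per_specimen = 200, seed = 11)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- default_cohort_config(cells_per_specimen = 200, seed = 12)
  expect_false(identical(generate_cohort(cfg), generate_cohort(cfg2)))
})

test_that("per-marker log means converge to the configured profile (4 SE)", {
  n <- 50000
  cfg <- single_profile_config(n, seed = 5)
  tab <- generate_cohort(cfg)
  pr <- cfg$profiles[[1]]
  se <- sqrt(diag(pr$log_cov) / n)
  for (m in names(pr$log_mean)) {
    expect_lt(abs(mean(log(tab[[m]])) - pr$log_mean[[m]]), 4 * se[[m]])
  }
})

test_that("empirical log covariance converges with cohort size", {
  pr_cov <- single_profile_config(10)$profiles[[1]]$log_cov
  frob <- function(n, seed) {
    tab <- generate_cohort(single_profile_config(n, seed = seed))
    logs <- log(as.matrix(as.data.frame(tab)[, markers(tab)]))
    sqrt(sum((cov(logs) - pr_cov)^2))
  }
  expect_lt(frob(50000, seed = 3), frob(1000, seed = 3))
})

test_that("aberrant cells lose 5mC and 5hmC and gain DAPI and AMACR", {
  tab <- generate_cohort(default_cohort_config(cells_per_specimen = 2000,
                                               seed = 2))
  e_cells <- tab[tab$compartment == "E", ]
  ac <- e_cells[e_cells$path_category == "AC", ]
  b <- e_cells[e_cells$path_category == "B", ]
  expect_lt(mean(log(ac$`5mC`)), mean(log(b$`5mC`)))
  expect_lt(mean(log(ac$`5hmC`)), mean(log(b$`5hmC`)))
  expect_gt(mean(log(ac$DAPI)), mean(log(b$DAPI)))
  expect_gt(mean(log(ac$AMACR)), mean(log(b$AMACR)))
  expect_lt(median(ac$`5mC`), median(b$`5mC`))
})

test_that("stromal compartment carries no class separation by default", {
  tab <- generate_cohort(default_cohort_config(cells_per_specimen = 2000,
                                               seed = 9))
  s_cells <- tab[tab$compartment == "S", ]
  ac <- s_cells[s_cells$path_category == "AC", ]
  b <- s_cells[s_cells$path_category == "B", ]
  # same generative profile: difference bounded by sampling noise
  pooled_se <- sqrt(var(log(s_cells$`5mC`)) * (1 / nrow(ac) + 1 / nrow(b)))
  expect_lt(abs(mean(log(ac$`5mC`)) - mean(log(b$`5mC`))), 4 * pooled_se)
})

test_that("profile_from_effects shifts the log mean and keeps the covariance", {
  base <- single_profile_config(10)$profiles[[1]]
  expect_equal(profile_from_effects(base, rep(0, 4))$log_mean, base$log_mean)
  doubled <- profile_from_effects(base, c(log(2), 0, 0, 0))
  # geometric mean of DAPI doubles, closed form
  expect_equal(exp(doubled$log_mean[["DAPI"]]), 2 * exp(base$log_mean[["DAPI"]]))
  expect_identical(doubled$log_cov, base$log_cov)
  expect_error(profile_from_effects(base, rep(0, 3)), "length")
})

test_that("invalid configurations are rejected", {
  lm4 <- c(DAPI = 6, AMACR = 5, `5mC` = 6, `5hmC` = 6)
  bad_cov <- diag(4) - 2 * diag(4)   # negative definite
  expect_error(class_profile("B", "B", "E", lm4, bad_cov, 1),
               "positive definite")
  good <- class_profile("B", "B", "E", lm4, diag(4) * 0.1, 0.5)
  expect_error(
    cohort_config(data.frame(specimen_id = "S", patient_id = "P",
                             phase = "biopsy1", cells = 10),
                  list(good)),
    "sum to 1")
  expect_error(class_profile("B", "B", "E", lm4, diag(4) * 0.1, 1.5), "0, 1")
})

test_that("clipping at the 12-bit ceiling is applied and flagged", {
  lm4 <- c(DAPI = 8.4, AMACR = 5, `5mC` = 6, `5hmC` = 6)  # exp(8.4) > 4095
  cfg <- single_profile_config(2000, seed = 4, log_mean = lm4)
  tab <- generate_cohort(cfg)
  expect_true(any(tab$clipped))
  expect_lte(max(tab$DAPI), 4095)
  expect_gt(min(tab$DAPI), 0)
})

test_that("specimen mixtures reshape class shares per specimen", {
  cfg <- default_cohort_config(cells_per_specimen = 3000, seed = 15)
  tab <- generate_cohort(cfg)
  b1 <- tab[tab$patient_id == "P3" & tab$phase == "biopsy1", ]
  expect_gt(mean(b1$path_category == "B"), 0.85)      # benign control biopsy
  pr <- tab[tab$patient_id == "P2" & tab$phase == "prostatectomy", ]
  expect_equal(mean(pr$path_category == "StageII"), 0.60, tolerance = 0.05)
  # compartment split preserved under reweighting (multinomial noise only)
  expect_equal(mean(pr$compartment == "E"), 0.40, tolerance = 0.05)
  expect_error(
    cohort_config(cfg$specimens, cfg$profiles,
                  specimen_mixtures = list(P9_b1 = c(B = 1))),
    "named by specimen_id")
  expect_error(
    cohort_config(cfg$specimens, cfg$profiles,
                  specimen_mixtures = list(P1_b1 = c(B = 0.5))),
    "sum to 1")
})

test_that("separable class profiles yield near-perfect logistic discrimination", {
  cfg <- default_cohort_config(cells_per_specimen = 1000, seed = 21,
                               effect_scale = 3)
  lt <- log_transform(generate_cohort(cfg))
  e_only <- filter_compartment(lt, "E")
  fit <- fit_logistic(e_only)
  r <- roc_auc(predict_prob(fit, e_only), aberrant_outcome(e_only))
  expect_gt(auc(r), 0.97)
})
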