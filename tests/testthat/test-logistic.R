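test_that("intercept-only fit recovers logit of the positive fraction", {
  tab <- make_table(cbind(DAPI = rep(5, 100)), log_scale = TRUE,
                    path_category = rep(c("AC", "B"), times = c(30, 70)))
  fit <- fit_logistic(tab, markers = character(0))
  expect_equal(unname(fit$beta), qlogis(0.3), tolerance = 1e-8)
})

test_that("the fitter recovers a known coefficient vector within 3 SE", {
  beta <- epithelial_truth_beta()
  tab <- generate_logistic_cohort(beta, n = 50000, seed = 314)
  fit <- fit_logistic(tab)
  se <- sqrt(diag(fit$cov_beta))
  expect_true(all(abs(fit$beta - beta) < 3 * se))
  expect_true(fit$converged)
})

test_that("coefficients agree with an independent reference fit to 1e-6", {
  tab <- generate_logistic_cohort(c(-1, 1.2, -0.8), n = 4000, seed = 5,
                                  log_mean = c(a = 0.5, b = 1))
  fit <- fit_logistic(tab)
  df <- as.data.frame(tab)
  ref <- glm(I(path_category != "B") ~ a + b, family = binomial(), data = df)
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(fit$cov_beta))),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-5)
})

test_that("degenerate outcomes are surfaced as errors", {
  tab <- make_table(cbind(DAPI = rnorm(50, 6)), log_scale = TRUE)  # all benign
  expect_error(fit_logistic(tab), "single-class")
  set.seed(1)
  x <- c(rnorm(50, -3), rnorm(50, 3))
  sep <- make_table(cbind(DAPI = x), log_scale = TRUE,
                    path_category = ifelse(x > 0, "AC", "B"))
  expect_error(fit_logistic(sep), "separation")
})

test_that("fitted probabilities sum to the number of aberrant cells", {
  tab <- generate_logistic_cohort(c(0.2, 0.8, -0.5), n = 2000, seed = 10,
                                  log_mean = c(a = 0, b = 0))
  fit <- fit_logistic(tab)
  probs <- predict_prob(fit, tab)
  expect_equal(sum(probs$prob_cancer), sum(aberrant_outcome(tab)),
               tolerance = 1e-6)
})

test_that("delta-method report reproduces printed z and CI columns", {
  for (model in ref_logistic_reports()) {
    rep <- coefficient_report(or = model$odds_ratio, se_or = model$se_or,
                              terms = model$term)
    # printed z and our recomputation both round the same unrounded value
    expect_true(all(abs(rep$z - model$z_printed) <= 0.011))
    expect_true(all(abs(rep$ci_low / model$ci_low_printed - 1) <= 2e-4))
    expect_true(all(abs(rep$ci_high / model$ci_high_printed - 1) <= 2e-4))
    expect_true(all(rep$ci_low < rep$odds_ratio & rep$odds_ratio < rep$ci_high))
    expect_equal(sign(rep$z), sign(log(rep$odds_ratio)))
  }
})

test_that("delta-method report handles the null coefficient and bad input", {
  rep <- coefficient_report(or = 1, se_or = 1)
  expect_equal(rep$odds_ratio, 1)
  expect_equal(rep$z, 0)
  expect_equal(rep$ci_low, exp(-1.959964))
  expect_equal(rep$ci_high, exp(1.959964))
  expect_error(coefficient_report(or = -2, se_or = 1), "positive")
  expect_error(coefficient_report(), "supply")
})

test_that("report from a fit matches the closed-form delta method", {
  tab <- generate_logistic_cohort(c(-0.5, 1), n = 3000, seed = 2,
                                  log_mean = c(a = 0))
  fit <- fit_logistic(tab)
  rep <- coefficient_report(fit)
  se_beta <- sqrt(diag(fit$cov_beta))
  expect_equal(rep$odds_ratio, unname(exp(fit$beta)))
  expect_equal(rep$se_or, unname(exp(fit$beta) * se_beta))
  expect_equal(rep$z, unname(fit$beta / se_beta))
})

test_that("probability predictions follow the inverse logit exactly", {
  beta <- epithelial_truth_beta()
  set.seed(77)
  x <- matrix(rnorm(40, 6, 0.5), 10, 4)
  colnames(x) <- c("DAPI", "AMACR", "5mC", "5hmC")
  tab <- make_table(x, log_scale = TRUE)
  fit <- structure(list(beta = setNames(beta, c("(Intercept)", colnames(x))),
                        cov_beta = diag(5),
                        marker_names = colnames(x), n_obs = 10,
                        converged = TRUE, n_iter = 0),
                   class = "logistic_fit")
  probs <- predict_prob(fit, tab)
  manual <- 1 / (1 + exp(-(beta[1] + x %*% beta[-1])))
  expect_equal(probs$prob_cancer, drop(manual), tolerance = 1e-10)
  expect_true(all(probs$prob_cancer >= 0 & probs$prob_cancer <= 1))

  zero_fit <- fit
  zero_fit$beta[] <- 0
  expect_true(all(predict_prob(zero_fit, tab)$prob_cancer == 0.5))
  expect_error(predict_prob(fit, make_table(cbind(Z = 1:5), log_scale = TRUE)),
               "marker")
})

test_that("univariate panel screens each marker separately", {
  cfg <- default_cohort_config(cells_per_specimen = 500, seed = 17)
  lt <- log_transform(generate_cohort(cfg))
  fits <- fit_univariate_panel(lt)
  expect_named(fits, markers(lt))
  for (f in fits) expect_length(f$beta, 2)
  # a marker carrying the class signal is strongly significant
  rep_5mc <- coefficient_report(fits[["5mC"]])
  expect_lt(rep_5mc$p_value[2], 1e-6)
})

test_that("type-I error is controlled for a null marker", {
  # marker independent of the outcome: |z| < 1.96 in >= 90% of repetitions
  hits <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    x <- rnorm(500, 6, 0.5)
    tab <- make_table(cbind(DAPI = x), log_scale = TRUE,
                      path_category = sample(c("B", "AC"), 500, replace = TRUE))
    fit <- fit_logistic(tab)
    abs(coefficient_report(fit)$z[2]) < 1.96
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("a marker that mirrors the outcome gives AUC near 1", {
  set.seed(3)
  y <- rep(0:1, each = 250)
  x <- y * 4 + rnorm(500, 6, 1)   # classes overlap slightly
  tab <- make_table(cbind(DAPI = x), log_scale = TRUE,
                    path_category = ifelse(y == 1, "AC", "B"))
  fit <- fit_logistic(tab)
  r <- roc_auc(predict_prob(fit, tab), y)
  expect_gt(auc(r), 0.99)
})
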