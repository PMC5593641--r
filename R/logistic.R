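#' Outcome rule: which cells count as aberrant
#'
#' The development data carries no per-cell ground truth; cells are labeled
#' by the diagnosis of their tissue of origin — every cell from malignant
#' tissue is treated as malignant, every cell from benign tissue as
#' normal. The default rule therefore marks a cell aberrant iff its
#' pathological category is not `"B"`.
#'
#' @param table A [cell_table()].
#' @return Integer vector of 0 (normal) / 1 (aberrant).
#' @export
aberrant_outcome <- function(table) {
  as.integer(table$path_category != "B")
}

#' Fit the binary cancer/normal logistic model
#'
#' Maximum-likelihood logistic regression of the aberrant-cell indicator
#' on the natural-log marker intensities, fitted by iteratively reweighted
#' least squares. Convergence is declared when the maximum absolute score
#' (gradient) falls below `1e-8` or the relative log-likelihood change
#' falls below `1e-10`. The coefficient covariance is the inverse observed
#' information at the MLE. Quasi-complete separation (diverging
#' coefficients) is surfaced as an error rather than silently regularized,
#' to keep estimates comparable with conventional reporting.
#'
#' @param table A log-transformed [cell_table()].
#' @param markers Predictor columns (default: all markers).
#' @param outcome Integer 0/1 vector, or a function of the table returning
#'   one (default [aberrant_outcome()]).
#' @param max_iter Iteration cap.
#' @return A `logistic_fit`: `beta` (named, intercept first), `cov_beta`,
#'   `marker_names`, `n_obs`, `converged`, `n_iter`, `loglik`.
#' @export
fit_logistic <- function(table, markers = NULL, outcome = aberrant_outcome,
                         max_iter = 100L) {
  stopifnot(inherits(table, "cell_table"))
  if (is.null(markers)) markers <- attr(table, "markers")
  y <- if (is.function(outcome)) outcome(table) else as.integer(outcome)
  if (length(y) != nrow(table)) stop("outcome length mismatch", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("outcome is single-class; both normal and aberrant cells required",
         call. = FALSE)
  }
  x <- as.matrix(as.data.frame(table, check.names = FALSE)[, markers, drop = FALSE])
  if (!all(is.finite(x))) stop("non-finite predictor values", call. = FALSE)
  irls_logistic(cbind(`(Intercept)` = 1, x), y, markers, max_iter)
}

# Numerically stable Bernoulli log-likelihood in the linear predictor.
bernoulli_loglik <- function(y, eta) {
  sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
}

irls_logistic <- function(X, y, marker_names, max_iter = 100L,
                          score_tol = 1e-8, loglik_tol = 1e-10) {
  p <- ncol(X)
  beta <- numeric(p)
  beta[1] <- stats::qlogis(max(min(mean(y), 1 - 1e-6), 1e-6))
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    score <- drop(crossprod(X, y - mu))
    ll <- bernoulli_loglik(y, eta)
    if (max(abs(score)) < score_tol ||
        (is.finite(ll_old) && abs(ll - ll_old) < loglik_tol * (abs(ll_old) + loglik_tol))) {
      converged <- TRUE
      break
    }
    if (max(abs(beta)) > 1e3) {
      stop("quasi-complete separation: coefficients diverge", call. = FALSE)
    }
    if (iter > max_iter) break
    info <- crossprod(X * w, X)
    step <- tryCatch(solve(info, score), error = function(e) {
      stop("information matrix is singular", call. = FALSE)
    })
    beta <- beta + step
    ll_old <- ll
  }
  if (!converged && max(abs(beta)) > 50) {
    stop("quasi-complete separation: coefficients diverge", call. = FALSE)
  }
  mu_fit <- stats::plogis(drop(X %*% beta))
  if (min(mu_fit[y == 1]) > 1 - 1e-7 && max(mu_fit[y == 0]) < 1e-7) {
    stop("quasi-complete separation: fitted probabilities are all 0/1",
         call. = FALSE)
  }
  eta <- drop(X %*% beta)
  w <- stats::plogis(eta) * (1 - stats::plogis(eta))
  cov_beta <- solve(crossprod(X * w, X))
  names(beta) <- colnames(X)
  dimnames(cov_beta) <- list(colnames(X), colnames(X))
  structure(list(beta = beta, cov_beta = cov_beta,
                 marker_names = marker_names, n_obs = nrow(X),
                 converged = converged, n_iter = iter,
                 loglik = bernoulli_loglik(y, eta)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> %d cells, %d predictors, %s in %d iterations\n",
              x$n_obs, length(x$marker_names),
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(coefficient_report(x), ...)
  invisible(x)
}

#' Univariate logistic panel screen
#'
#' One single-predictor logistic fit per marker, the screening step that
#' establishes which individual markers are significantly associated with
#' aberrant cells before the multivariate model is fitted.
#'
#' @inheritParams fit_logistic
#' @return Named list of `logistic_fit`, one per marker.
#' @export
fit_univariate_panel <- function(table, markers = NULL,
                                 outcome = aberrant_outcome) {
  stopifnot(inherits(table, "cell_table"))
  if (is.null(markers)) markers <- attr(table, "markers")
  fits <- lapply(markers, function(m) fit_logistic(table, m, outcome))
  names(fits) <- markers
  fits
}

#' Delta-method odds-ratio report for a logistic fit
#'
#' Standard reporting layout for logistic coefficients: per predictor the
#' odds ratio `exp(beta)`, its delta-method standard error
#' `SE(OR) = OR * SE(beta)`, the Wald statistic `z = beta / SE(beta)`, the
#' two-sided normal p-value, and the 95% interval
#' `exp(beta +/- 1.959964 * SE(beta))`. The same arithmetic can be run
#' backwards from a published `(OR, SE(OR))` pair — `SE(beta) = SE(OR)/OR`
#' — to recompute the z and interval columns of a printed table.
#'
#' @param fit A `logistic_fit`, or `NULL` when `or`/`se_or` are given.
#' @param or,se_or Optional numeric vectors of printed odds ratios and
#'   their delta-method standard errors (used instead of `fit`).
#' @param terms Optional term names for the `or`/`se_or` route.
#' @return A tibble with columns `term`, `odds_ratio`, `se_or`, `z`,
#'   `p_value`, `ci_low`, `ci_high`.
#' @export
coefficient_report <- function(fit = NULL, or = NULL, se_or = NULL,
                               terms = NULL) {
  zcrit <- 1.959964
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "logistic_fit"))
    beta <- fit$beta
    se_beta <- sqrt(diag(fit$cov_beta))
    terms <- names(beta)
  } else {
    if (is.null(or) || is.null(se_or)) {
      stop("supply either a fit or (or, se_or) pairs", call. = FALSE)
    }
    if (any(or <= 0)) stop("odds ratios must be positive", call. = FALSE)
    if (any(se_or <= 0)) stop("standard errors must be positive", call. = FALSE)
    beta <- log(or)
    se_beta <- se_or / or
    if (is.null(terms)) terms <- paste0("term", seq_along(or))
  }
  odds <- unname(exp(beta))
  se_beta <- unname(se_beta)
  beta <- unname(beta)
  z <- beta / se_beta
  tibble::tibble(
    term = terms,
    odds_ratio = odds,
    se_or = odds * se_beta,
    z = z,
    p_value = 2 * stats::pnorm(-abs(z)),
    ci_low = exp(beta - zcrit * se_beta),
    ci_high = exp(beta + zcrit * se_beta)
  )
}

#' Per-cell cancer probabilities from a fitted model
#'
#' Inverse-logit evaluation of the fitted linear predictor: for each cell
#' the model estimates the probability that the cell is cancerous.
#'
#' @param fit A `logistic_fit`.
#' @param table A log-transformed [cell_table()] carrying the fitted
#'   markers.
#' @param cutoff Optional probability cutoff; when given, a
#'   `predicted_label` column (`"normal"`/`"aberrant"`, aberrant iff
#'   `prob >= cutoff`) is added.
#' @return A tibble: `cell_id`, `linear_predictor`, `prob_cancer` (and
#'   `predicted_label` when `cutoff` is given).
#' @export
predict_prob <- function(fit, table, cutoff = NULL) {
  stopifnot(inherits(fit, "logistic_fit"), inherits(table, "cell_table"))
  if (!all(fit$marker_names %in% attr(table, "markers"))) {
    stop("table does not carry the fitted marker set", call. = FALSE)
  }
  x <- as.matrix(as.data.frame(table, check.names = FALSE)[, fit$marker_names,
                                                           drop = FALSE])
  eta <- unname(drop(cbind(1, x) %*% fit$beta))
  out <- tibble::tibble(
    cell_id = table$cell_id,
    linear_predictor = eta,
    prob_cancer = stats::plogis(eta)
  )
  if (!is.null(cutoff)) {
    out$predicted_label <- ifelse(out$prob_cancer >= cutoff,
                                  "aberrant", "normal")
  }
  out
}
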