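# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Round half away from zero (display convention for composition tables).
# A tiny guard absorbs binary representation error just below a .5 boundary.
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Derive a per-stage seed from a global pipeline seed
#'
#' Pipeline stages draw their randomness from seeds expanded out of one
#' global seed by a fixed counter scheme, so any stage can be rerun in
#' isolation and still match a full pipeline run.
#'
#' @param seed Integer global seed.
#' @param stage Integer stage counter (>= 1).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(stage))
  as.integer((abs(as.numeric(seed)) %% 1e6) * 2011 + 7919 * as.numeric(stage)) %% 2147483629L
}

# Draw n samples from a multivariate normal via Cholesky factorization.
# Deterministic given the RNG state (column-ordered rnorm fill).
rmvnorm_chol <- function(n, mean, sigma) {
  p <- length(mean)
  R <- tryCatch(chol(sigma), error = function(e) {
    stop("covariance matrix is not positive definite", call. = FALSE)
  })
  z <- matrix(stats::rnorm(n * p), nrow = n, ncol = p)
  sweep(z %*% R, 2, mean, "+")
}

# Largest-remainder (Hamilton) apportionment of `total` into shares `w`.
largest_remainder <- function(total, w) {
  w <- w / sum(w)
  raw <- total * w
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}
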