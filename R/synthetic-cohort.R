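#' Class- and compartment-conditional generative profile
#'
#' A `class_profile` holds the parameters of the multivariate log-normal
#' distribution that generates intensities for one (pathological class,
#' Gleason group, compartment) stratum: channel intensities in tissue are
#' strongly right-skewed, and their natural logs are modeled as
#' multivariate normal.
#'
#' @param path_category One of [path_categories].
#' @param gleason_group One of [gleason_groups].
#' @param compartment One of [cell_compartments], or `NA` for cultured cells.
#' @param log_mean Named numeric vector of per-marker natural-log intensity
#'   means (log-intensity units).
#' @param log_cov Symmetric positive-definite covariance of log intensities
#'   (marker order identical to `log_mean`).
#' @param cell_fraction Expected share of cohort cells drawn from this
#'   profile, in \[0, 1\].
#' @return A `class_profile`.
#' @export
class_profile <- function(path_category, gleason_group, compartment,
                          log_mean, log_cov, cell_fraction) {
  stopifnot(path_category %in% path_categories,
            gleason_group %in% gleason_groups,
            is.na(compartment) || compartment %in% cell_compartments)
  log_mean <- unlist(log_mean)
  if (is.null(names(log_mean))) stop("log_mean must be named by marker", call. = FALSE)
  log_cov <- as.matrix(log_cov)
  p <- length(log_mean)
  if (!all(dim(log_cov) == p)) stop("log_cov dimension mismatch", call. = FALSE)
  if (max(abs(log_cov - t(log_cov))) > 1e-10) {
    stop("log_cov is not symmetric", call. = FALSE)
  }
  ev <- eigen(log_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("log_cov is not positive definite", call. = FALSE)
  if (cell_fraction < 0 || cell_fraction > 1) {
    stop("cell_fraction must be in [0, 1]", call. = FALSE)
  }
  structure(list(path_category = path_category, gleason_group = gleason_group,
                 compartment = compartment, log_mean = log_mean,
                 log_cov = log_cov, cell_fraction = cell_fraction),
            class = "class_profile")
}

#' Shift a profile by per-marker log fold changes
#'
#' Convenience for encoding directional class effects: the returned profile
#' has `log_mean = baseline$log_mean + log_fold_changes` and the same
#' covariance, so a shift of `+ln(2)` on a marker doubles its geometric
#' mean intensity.
#'
#' @param baseline A [class_profile()].
#' @param log_fold_changes Numeric vector, one entry per marker (recycled
#'   names are checked when present).
#' @param ... Fields of the returned profile to override
#'   (`path_category`, `gleason_group`, `compartment`, `cell_fraction`).
#' @return A `class_profile`.
#' @export
profile_from_effects <- function(baseline, log_fold_changes, ...) {
  stopifnot(inherits(baseline, "class_profile"))
  if (length(log_fold_changes) != length(baseline$log_mean)) {
    stop("log_fold_changes length does not match marker count", call. = FALSE)
  }
  if (!is.null(names(log_fold_changes)) &&
      !identical(names(log_fold_changes), names(baseline$log_mean))) {
    stop("log_fold_changes names do not match marker order", call. = FALSE)
  }
  over <- list(...)
  args <- utils::modifyList(
    list(path_category = baseline$path_category,
         gleason_group = baseline$gleason_group,
         compartment = baseline$compartment,
         cell_fraction = baseline$cell_fraction),
    over
  )
  lm <- baseline$log_mean + as.numeric(log_fold_changes)
  class_profile(args$path_category, args$gleason_group, args$compartment,
                lm, baseline$log_cov, args$cell_fraction)
}

#' Cohort simulation configuration
#'
#' @param specimens Data frame with columns `specimen_id`, `patient_id`,
#'   `phase` and `cells` (cell count per specimen, >= 1).
#' @param profiles List of [class_profile()]s sharing one marker order;
#'   their `cell_fraction`s must sum to 1 (the same mixture is used within
#'   every specimen).
#' @param intensity_scale Maximum representable intensity; 4095 for the
#'   12-bit acquisition scale.
#' @param specimen_mixtures Optional named list (`specimen_id` ->
#'   named class-weight vector over pathological categories, summing to 1)
#'   overriding, per specimen, the class shares implied by the profiles;
#'   the compartment split within each class is preserved. Specimens
#'   without an entry use the profile fractions unchanged.
#' @param seed Integer seed; a fixed seed makes generation byte-identical.
#' @return A `cohort_config`.
#' @export
cohort_config <- function(specimens, profiles, intensity_scale = 4095,
                          specimen_mixtures = NULL, seed = 1L) {
  specimens <- as.data.frame(specimens)
  stopifnot(all(c("specimen_id", "patient_id", "phase", "cells") %in%
                  names(specimens)),
            all(specimens$phase %in% cell_phases),
            all(specimens$cells >= 1))
  if (length(profiles) == 0) stop("at least one profile required", call. = FALSE)
  mk <- names(profiles[[1]]$log_mean)
  for (pr in profiles) {
    stopifnot(inherits(pr, "class_profile"))
    if (!identical(names(pr$log_mean), mk)) {
      stop("all profiles must share one marker order", call. = FALSE)
    }
  }
  fr <- sum(vapply(profiles, function(p) p$cell_fraction, numeric(1)))
  if (abs(fr - 1) > 1e-8) {
    stop("profile cell_fractions must sum to 1 (got ", signif(fr, 6), ")",
         call. = FALSE)
  }
  classes <- vapply(profiles, function(p) p$path_category, character(1))
  if (!is.null(specimen_mixtures)) {
    if (is.null(names(specimen_mixtures)) ||
        !all(names(specimen_mixtures) %in% specimens$specimen_id)) {
      stop("specimen_mixtures must be named by specimen_id", call. = FALSE)
    }
    for (mx in specimen_mixtures) {
      if (abs(sum(mx) - 1) > 1e-8 || any(mx < 0)) {
        stop("each specimen mixture must be nonnegative and sum to 1",
             call. = FALSE)
      }
      if (!all(names(mx) %in% classes)) {
        stop("mixture class(es) not covered by the profiles: ",
             paste(setdiff(names(mx), classes), collapse = ", "),
             call. = FALSE)
      }
    }
  }
  structure(list(specimens = specimens, profiles = profiles,
                 markers = mk, intensity_scale = intensity_scale,
                 specimen_mixtures = specimen_mixtures,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Per-specimen profile weights: profile fractions, reweighted so the class
# marginals match the specimen's mixture while the compartment split
# within each class is untouched.
specimen_profile_weights <- function(config, specimen_id) {
  base <- vapply(config$profiles, function(p) p$cell_fraction, numeric(1))
  mix <- config$specimen_mixtures[[specimen_id]]
  if (is.null(mix)) return(base)
  classes <- vapply(config$profiles, function(p) p$path_category, character(1))
  class_tot <- tapply(base, classes, sum)
  w <- numeric(length(base))
  for (j in seq_along(base)) {
    target <- if (classes[j] %in% names(mix)) mix[[classes[j]]] else 0
    w[j] <- if (class_tot[[classes[j]]] > 0)
      base[j] * target / class_tot[[classes[j]]] else 0
  }
  w
}

#' Generate a synthetic per-cell intensity cohort
#'
#' Draws, for every specimen, profile-conditional multivariate log-normal
#' intensities: cell counts per profile by multinomial allocation of the
#' specimen's cells over the profile `cell_fraction`s, log intensities from
#' `N(log_mean, log_cov)`, then exponentiation. Intensities above
#' `intensity_scale` are clipped to the ceiling and the affected cells
#' flagged in a `clipped` column. Generation is exactly reproducible for a
#' fixed config seed.
#'
#' @param config A [cohort_config()].
#' @return A [cell_table()] with one row per simulated nucleus and a
#'   `clipped` logical column.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    parts <- vector("list", nrow(config$specimens) * length(config$profiles))
    idx <- 0
    for (s in seq_len(nrow(config$specimens))) {
      sp <- config$specimens[s, ]
      counts <- as.integer(stats::rmultinom(
        1, sp$cells, specimen_profile_weights(config, sp$specimen_id)
      ))
      offset <- 0
      for (j in seq_along(config$profiles)) {
        n <- counts[j]
        if (n == 0) next
        pr <- config$profiles[[j]]
        logs <- rmvnorm_chol(n, pr$log_mean, pr$log_cov)
        vals <- exp(logs)
        clipped <- apply(vals > config$intensity_scale, 1, any)
        vals <- pmin(vals, config$intensity_scale)
        idx <- idx + 1
        df <- data.frame(
          cell_id = sprintf("%s_c%05d", sp$specimen_id, offset + seq_len(n)),
          patient_id = sp$patient_id,
          phase = sp$phase,
          frame_id = sprintf("%s_f1", sp$specimen_id),
          compartment = pr$compartment,
          path_category = pr$path_category,
          gleason_group = pr$gleason_group,
          stringsAsFactors = FALSE
        )
        colnames(vals) <- config$markers
        df <- cbind(df, as.data.frame(vals, check.names = FALSE))
        df$clipped <- clipped
        offset <- offset + n
        parts[[idx]] <- df
      }
    }
    out <- do.call(rbind, parts[seq_len(idx)])
    rownames(out) <- NULL
    cell_table(out, config$markers,
               provenance = list(source = "generate_cohort",
                                 seed = config$seed,
                                 intensity_scale = config$intensity_scale))
  })
}

# Default generative geometry for the four-marker panel
# (DAPI, AMACR, 5mC, 5hmC). Means/dispersions are package choices on the
# 12-bit scale; the aberrant-class effect directions encode the observed
# contrasts: DNA content (DAPI) and AMACR up, 5mC and 5hmC down.
panel_i_markers <- c("DAPI", "AMACR", "5mC", "5hmC")

default_log_cov <- function() {
  sds <- c(DAPI = 0.35, AMACR = 0.55, `5mC` = 0.50, `5hmC` = 0.50)
  R <- diag(4)
  dimnames(R) <- list(panel_i_markers, panel_i_markers)
  R["5mC", "5hmC"] <- R["5hmC", "5mC"] <- 0.50
  R["DAPI", "5mC"] <- R["5mC", "DAPI"] <- 0.20
  R["DAPI", "5hmC"] <- R["5hmC", "DAPI"] <- 0.20
  R["AMACR", "DAPI"] <- R["DAPI", "AMACR"] <- 0.10
  diag(sds) %*% R %*% diag(sds)
}

default_benign_log_mean <- function() {
  c(DAPI = 6.40, AMACR = 5.20, `5mC` = 6.10, `5hmC` = 5.90)
}

# Aberrant effect (log units) at full strength; scaled per class severity
# and attenuated toward the stromal compartment.
default_aberrant_effect <- function() {
  c(DAPI = 0.45, AMACR = 0.35, `5mC` = -0.90, `5hmC` = -0.70)
}

#' Default synthetic cohort configurations
#'
#' `default_cohort_config()` emulates the structure of the development
#' cohort: five patients sampled at biopsy and prostatectomy, frames across
#' all four tissue compartments (40/30/20/10 E, E+s, ES, S), six
#' pathological classes, and a monotone severity gradient of the aberrant
#' effect (DAPI and AMACR up, 5mC and 5hmC down in aberrant cells). Each
#' specimen carries its own diagnosis-dominated class mixture — one benign
#' biopsy serves as the healthy control, biopsies of the other patients
#' are dominated by adenocarcinoma-spectrum cells, prostatectomies by
#' stage II/III cells, each with a benign admixture — giving an overall
#' benign share near one quarter. Class separation is attenuated toward
#' the stroma and vanishes in the pure stromal compartment, where the
#' markers show no class covariation. Cohort size defaults to a
#' desk-scale fraction of the full ~139k-cell database and is configurable
#' via `cells_per_specimen`.
#'
#' `null_cohort_config()` is the matching negative control: identical
#' generative profiles for every class (zero effect, equal class shares),
#' under which any downstream discrimination is spurious.
#'
#' `culture_cohort_config()` mimics the two cultured validation cell types:
#' a normal primary epithelial culture (benign profile) and an
#' adenocarcinoma line (fully aberrant profile), with missing compartment.
#'
#' @param cells_per_specimen Cells per specimen (scalar or one per
#'   specimen).
#' @param effect_scale Multiplier on the aberrant effect vector (1 =
#'   default separation; 0 = null).
#' @param seed Integer seed.
#' @return A [cohort_config()].
#' @export
default_cohort_config <- function(cells_per_specimen = 1500, seed = 1L,
                                  effect_scale = 1) {
  specimens <- expand.grid(
    phase = c("biopsy1", "prostatectomy"),
    patient_id = paste0("P", 1:5),
    stringsAsFactors = FALSE
  )
  specimens$specimen_id <- paste0(specimens$patient_id, "_",
                                  ifelse(specimens$phase == "biopsy1", "b1", "pr"))
  specimens$cells <- cells_per_specimen
  biopsy_lac <- c(LAC = 0.60, B = 0.15, AC = 0.15, ASAP = 0.10)
  prost_ii <- c(StageII = 0.60, B = 0.15, StageIII = 0.15, AC = 0.10)
  prost_iii <- c(StageIII = 0.60, B = 0.15, StageII = 0.15, LAC = 0.10)
  mixtures <- list(
    P1_b1 = c(ASAP = 0.55, B = 0.25, AC = 0.20),   # atypical + focal cancer
    P1_pr = prost_iii,
    P2_b1 = biopsy_lac, P2_pr = prost_ii,
    P3_b1 = c(B = 0.92, ASAP = 0.08),              # the benign control biopsy
    P3_pr = prost_iii,
    P4_b1 = biopsy_lac, P4_pr = prost_ii,
    P5_b1 = biopsy_lac, P5_pr = prost_iii
  )
  cohort_config(
    specimens = specimens[, c("specimen_id", "patient_id", "phase", "cells")],
    profiles = gradient_profiles(effect_scale = effect_scale),
    specimen_mixtures = mixtures,
    seed = seed
  )
}

# Class mixture and severity gradient shared by the default configs.
class_mixture <- function(equal = FALSE) {
  classes <- data.frame(
    path_category = c("B", "ASAP", "AC", "LAC", "StageII", "StageIII"),
    gleason_group = c("B", "B", "G33", "G34", "G34", "G43"),
    severity = c(0, 0.35, 1.0, 1.25, 1.5, 1.75),
    fraction = c(0.215, 0.10, 0.17, 0.205, 0.155, 0.155),
    stringsAsFactors = FALSE
  )
  if (equal) classes$fraction <- rep(1 / 6, 6)
  classes
}

gradient_profiles <- function(effect_scale = 1, equal_fractions = FALSE) {
  comp <- data.frame(
    compartment = c("E", "E+s", "ES", "S"),
    frac = c(0.40, 0.30, 0.20, 0.10),
    attenuation = c(1.0, 0.7, 0.4, 0.0),
    stringsAsFactors = FALSE
  )
  classes <- class_mixture(equal = equal_fractions)
  eff <- default_aberrant_effect()
  base_mean <- default_benign_log_mean()
  cov <- default_log_cov()
  profiles <- list()
  for (ci in seq_len(nrow(comp))) {
    for (ki in seq_len(nrow(classes))) {
      shift <- eff * classes$severity[ki] * comp$attenuation[ci] * effect_scale
      profiles[[length(profiles) + 1]] <- class_profile(
        path_category = classes$path_category[ki],
        gleason_group = classes$gleason_group[ki],
        compartment = comp$compartment[ci],
        log_mean = base_mean + shift,
        log_cov = cov,
        cell_fraction = comp$frac[ci] * classes$fraction[ki]
      )
    }
  }
  profiles
}

#' @rdname default_cohort_config
#' @export
null_cohort_config <- function(cells_per_specimen = 600, seed = 1L) {
  specimens <- expand.grid(
    phase = c("biopsy1", "prostatectomy"),
    patient_id = paste0("P", 1:5),
    stringsAsFactors = FALSE
  )
  specimens$specimen_id <- paste0(specimens$patient_id, "_",
                                  ifelse(specimens$phase == "biopsy1", "b1", "pr"))
  specimens$cells <- cells_per_specimen
  cohort_config(
    specimens = specimens[, c("specimen_id", "patient_id", "phase", "cells")],
    profiles = gradient_profiles(effect_scale = 0, equal_fractions = TRUE),
    seed = seed
  )
}

#' @rdname default_cohort_config
#' @param n_normal,n_cancer Cells for the normal-culture and cancer-line
#'   specimens.
#' @export
culture_cohort_config <- function(n_normal = 2000, n_cancer = 2000,
                                  seed = 1L) {
  eff <- default_aberrant_effect()
  base <- class_profile("B", "B", NA, default_benign_log_mean(),
                        default_log_cov(), 1)
  cancer <- profile_from_effects(base, eff * 1.5, path_category = "StageII",
                                 gleason_group = "G34")
  specimens <- data.frame(
    specimen_id = c("HPrEpiC_like", "LNCaP_like"),
    patient_id = c("CultureN", "CultureC"),
    phase = "culture",
    cells = c(n_normal, n_cancer),
    stringsAsFactors = FALSE
  )
  # one config per specimen type would duplicate plumbing; instead give
  # each profile half weight and post-filter by patient when needed
  cfg_n <- cohort_config(specimens[1, ], list(base), seed = seed)
  cfg_c <- cohort_config(specimens[2, ],
                         list(profile_from_effects(cancer, rep(0, 4),
                                                   cell_fraction = 1)),
                         seed = seed + 1L)
  list(normal = cfg_n, cancer = cfg_c)
}

#' Simulate cells from a known logistic truth
#'
#' Parameter-recovery design: log intensities are drawn multivariate
#' normal, and each cell's aberrant label is Bernoulli with probability
#' `plogis(beta0 + x' beta)`. Used to verify that the fitter recovers a
#' known coefficient vector (for example the published epithelial-model
#' log odds ratios) within its reported standard errors. The returned
#' table is already on the natural-log scale.
#'
#' @param beta Numeric vector `c(intercept, per-marker slopes)` on the
#'   log-odds scale.
#' @param n Number of cells.
#' @param log_mean,log_cov Mean/covariance of the log intensities; defaults
#'   center the linear predictor near zero spread over a few logits.
#' @param seed Integer seed.
#' @return A log-scale [cell_table()] where aberrant cells carry
#'   `path_category = "AC"` and normal cells `"B"`.
#' @export
generate_logistic_cohort <- function(beta, n,
                                     log_mean = rep(6, length(beta) - 1),
                                     log_cov = diag(0.25, length(beta) - 1),
                                     seed = 1L) {
  p <- length(beta) - 1
  stopifnot(p >= 1, length(log_mean) == p, all(dim(as.matrix(log_cov)) == p))
  mk <- if (!is.null(names(log_mean))) names(log_mean) else
    panel_i_markers[seq_len(p)]
  with_seed(seed, {
    x <- rmvnorm_chol(n, log_mean, as.matrix(log_cov))
    colnames(x) <- mk
    lp <- drop(beta[1] + x %*% beta[-1])
    y <- stats::rbinom(n, 1, stats::plogis(lp))
    df <- data.frame(
      cell_id = sprintf("sim_c%06d", seq_len(n)),
      patient_id = "SIM",
      phase = "biopsy1",
      frame_id = "sim_f1",
      compartment = "E",
      path_category = ifelse(y == 1, "AC", "B"),
      gleason_group = ifelse(y == 1, "G33", "B"),
      stringsAsFactors = FALSE
    )
    df <- cbind(df, as.data.frame(x, check.names = FALSE))
    tab <- cell_table(df, mk,
                      provenance = list(source = "generate_logistic_cohort",
                                        seed = seed, log_transformed = TRUE,
                                        truth_beta = as.numeric(beta)))
    tab
  })
}
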