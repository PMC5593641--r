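#' Published reference values used in worked examples
#'
#' `ref_logistic_reports()` returns the printed odds-ratio / standard-error
#' rows of the two published development logistic models for the
#' four-marker panel — the epithelial-cells-only model and the all-cells
#' model — together with the printed Wald z and 95% interval columns.
#' These are inputs for worked-example consistency checks: feeding the
#' `(OR, SE)` pairs through [coefficient_report()] must reproduce the
#' printed z and interval columns, since all four are linked by the delta
#' method.
#'
#' `ref_validation_counts()` returns published specimen-level cell-call
#' counts (normal culture vs cancer line, epithelial-only logistic model,
#' and the 30,000-cell k-NN pathological-category classification) used as
#' worked examples for the composition-table formatter.
#'
#' @return `ref_logistic_reports()`: a named list of two data frames
#'   (`epithelial`, `all_cells`) with columns `term`, `odds_ratio`,
#'   `se_or`, `z_printed`, `ci_low_printed`, `ci_high_printed`.
#'   `ref_validation_counts()`: a named list of count vectors.
#' @export
ref_logistic_reports <- function() {
  list(
    epithelial = data.frame(
      term = c("lnDAPI", "lnAMACR", "ln5mC", "ln5hmC", "(Intercept)"),
      odds_ratio = c(7.224606, 0.199478, 0.0199724, 2.95159, 490131.5),
      se_or = c(0.2921743, 0.0132372, 0.0017131, 0.2216339, 201505.3),
      z_printed = c(48.9, -24.29, -45.63, 14.41, 31.87),
      ci_low_printed = c(6.674063, 0.1751499, 0.0168818, 2.547649, 218958.8),
      ci_high_printed = c(7.820565, 0.2271852, 0.0236286, 3.419578, 1097142),
      stringsAsFactors = FALSE
    ),
    all_cells = data.frame(
      term = c("lnDAPI", "lnAMACR", "ln5mC", "ln5hmC", "(Intercept)"),
      odds_ratio = c(6.459606, 0.4555956, 0.0290629, 3.055547, 3845.418),
      se_or = c(0.1339882, 0.0120028, 0.0009604, 0.0929042, 650.8334),
      z_printed = c(89.94, -29.84, -107.08, 36.74, 48.77),
      ci_low_printed = c(6.20226, 0.4326676, 0.0272403, 2.878778, 2759.806),
      ci_high_printed = c(6.727629, 0.4797386, 0.0310075, 3.243171, 5358.073),
      stringsAsFactors = FALSE
    )
  )
}

#' @rdname ref_logistic_reports
#' @export
ref_validation_counts <- function() {
  list(
    # epithelial-only logistic calls: (normal, aberrant)
    logistic_epithelial = list(
      HPrEpiC = c(No = 1800, Yes = 266),     # printed %: 87.12 / 12.88
      LNCaP = c(No = 148, Yes = 17289)       # printed %: 0.85 / 99.15
    ),
    # 30,000-cell k-NN pathological-category calls
    knn_subsample_path = list(
      HPrEpiC = c(B = 1613, ASAP = 20, AC = 221, StageII = 35,
                  StageIII = 16, LAC = 106),
      # printed %: 80.21 / 0.99 / 10.99 / 1.74 / 0.80 / 5.27
      LNCaP = c(B = 78, ASAP = 262, AC = 430, StageII = 14681,
                StageIII = 264, LAC = 1220)
      # printed %: 0.46 / 1.55 / 2.54 / 86.69 / 1.56 / 7.20
    )
  )
}
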