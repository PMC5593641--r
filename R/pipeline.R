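#' End-to-end pipeline configuration
#'
#' Bundles every stage setting of the cell-by-cell classification
#' pipeline: cohort source, marker panel, compartment filter for the
#' logistic stage, cutoff preset, k-NN settings, and the global seed. The
#' global seed is expanded into per-stage seeds with [stage_seed()]
#' (counters: 1 simulate, 2 logistic, 3 k-NN), so a stage can be rerun in
#' isolation and reproduce its part of a full run. Two operating-cutoff
#' presets are shipped, matching the published models:
#' `cutoff_preset = "epithelial"` (0.75) and `"all_cells"` (0.9);
#' `NULL` selects the cutoff from the scan by the Youden rule.
#'
#' @param cohort A [cohort_config()], or a `cell_table` to use as-is.
#' @param markers Marker panel (default: the cohort's markers).
#' @param compartment_filter Compartments for the logistic stage (`NULL` =
#'   all cells).
#' @param cutoff_preset `"epithelial"`, `"all_cells"`, a number in (0,1),
#'   or `NULL` for Youden selection from the scan.
#' @param knn_label_scheme `"path_category"` or `"gleason_group"`.
#' @param knn_k,knn_subsample k-NN neighbor count and reference cap.
#' @param development_patients Patients used for fitting; default: all.
#' @param seed Global integer seed.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(cohort, markers = NULL, compartment_filter = NULL,
                            cutoff_preset = NULL,
                            knn_label_scheme = "path_category",
                            knn_k = 5L, knn_subsample = 30000L,
                            development_patients = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config") || inherits(cohort, "cell_table"))
  cutoff <- resolve_cutoff_preset(cutoff_preset)
  structure(list(cohort = cohort, markers = markers,
                 compartment_filter = compartment_filter,
                 cutoff = cutoff,
                 knn_label_scheme = knn_label_scheme,
                 knn_k = as.integer(knn_k),
                 knn_subsample = as.integer(knn_subsample),
                 development_patients = development_patients,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

resolve_cutoff_preset <- function(preset) {
  if (is.null(preset)) return(NULL)
  if (is.character(preset)) {
    return(switch(preset,
                  epithelial = 0.75,
                  all_cells = 0.9,
                  stop("unknown cutoff preset '", preset, "'", call. = FALSE)))
  }
  stopifnot(is.numeric(preset), preset > 0, preset < 1)
  preset
}

#' Run the full cell-by-cell classification pipeline
#'
#' Executes simulate/ingest, log transform, optional compartment filter,
#' logistic scoring (fit, delta-method report, cutoff scan, ROC + band),
#' Mahalanobis k-NN staging, and fuzzy-logic specimen aggregation, and
#' returns one evaluation report. A rerun with the same config (and seed)
#' reproduces the report exactly.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, the stage outputs are
#'   written there as CSV/JSON.
#' @return A `pipeline_report` list: `coefficients`, `cutoff_scan`,
#'   `cutoff`, `auc`, `band`, `sensitivity`, `specificity`,
#'   `percent_correct`, `knn_evaluation`, `logistic_compositions`,
#'   `knn_compositions`, `diagnoses`, `provenance`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  # stage 1: cohort
  cohort <- if (inherits(config$cohort, "cell_table")) config$cohort else {
    cfg <- config$cohort
    cfg$seed <- stage_seed(config$seed, 1)
    generate_cohort(cfg)
  }
  markers <- if (is.null(config$markers)) attr(cohort, "markers") else config$markers
  logt <- if (isTRUE(provenance(cohort)$log_transformed)) cohort else
    log_transform(cohort)

  dev <- if (is.null(config$development_patients)) logt else {
    split_development_validation(
      logt, config$development_patients,
      setdiff(unique(logt$patient_id), config$development_patients)
    )$development
  }

  # stage 2: logistic scoring (optionally on a compartment subset)
  log_table <- if (is.null(config$compartment_filter)) dev else
    filter_compartment(dev, config$compartment_filter)
  fit <- fit_logistic(log_table, markers)
  truth <- aberrant_outcome(log_table)
  probs <- predict_prob(fit, log_table)
  scan <- cutoff_scan(probs, truth)
  cutoff <- if (is.null(config$cutoff)) select_cutoff(scan) else config$cutoff
  roc <- roc_auc(probs, truth)
  at_cut <- scan[abs(scan$cutoff - cutoff) < 1e-9, ]
  if (nrow(at_cut) == 0) {
    pred <- probs$prob_cancer >= cutoff
    at_cut <- tibble::tibble(
      sensitivity = sum(pred & truth == 1) / sum(truth == 1),
      specificity = sum(!pred & truth == 0) / sum(truth == 0),
      percent_correct = 100 * mean((probs$prob_cancer >= cutoff) == (truth == 1))
    )
  }

  # stage 3: k-NN staging over all development cells
  knn <- build_knn(dev, config$knn_label_scheme, k = config$knn_k,
                   subsample_size = config$knn_subsample,
                   seed = stage_seed(config$seed, 3), markers = markers)
  knn_res <- classify_cells(knn, dev)
  knn_eval <- knn_accuracy_heatmap(knn_res, dev[[config$knn_label_scheme]])

  # stage 4: specimen-level aggregation
  specimen <- paste(dev$patient_id, dev$phase, sep = "_")
  probs_lab <- ifelse(probs$prob_cancer >= cutoff, "aberrant", "normal")
  idx_log <- paste(log_table$patient_id, log_table$phase, sep = "_")
  logistic_comp <- lapply(split(probs_lab, idx_log), function(l)
    compose(l, class_order = c("normal", "aberrant")))
  for (nm in names(logistic_comp)) logistic_comp[[nm]]$specimen_id <- nm
  knn_comp <- lapply(split(knn_res$assigned_label, specimen), compose)
  for (nm in names(knn_comp)) knn_comp[[nm]]$specimen_id <- nm
  sev <- if (config$knn_label_scheme == "path_category") path_severity else
    gleason_severity
  diagnoses <- lapply(knn_comp, majority_diagnosis, severity_order = sev)

  report <- structure(list(
    coefficients = coefficient_report(fit),
    fit = fit,
    cutoff_scan = scan,
    cutoff = cutoff,
    auc = auc(roc),
    band = discrimination_band(auc(roc)),
    sensitivity = at_cut$sensitivity[1],
    specificity = at_cut$specificity[1],
    percent_correct = at_cut$percent_correct[1],
    knn_evaluation = knn_eval,
    logistic_compositions = logistic_comp,
    knn_compositions = knn_comp,
    diagnoses = diagnoses,
    provenance = list(seed = config$seed,
                      n_cells = nrow(dev),
                      n_logistic_cells = nrow(log_table),
                      markers = markers,
                      compartment_filter = config$compartment_filter,
                      knn_label_scheme = config$knn_label_scheme)
  ), class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$coefficients, file.path(out_dir, "coefficients.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$cutoff_scan),
                   file.path(out_dir, "cutoff_scan.csv"), row.names = FALSE)
  classes <- sort(unique(unlist(lapply(report$knn_compositions,
                                       function(cp) names(cp$counts)))))
  utils::write.csv(composition_table(report$knn_compositions, classes),
                   file.path(out_dir, "knn_compositions.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(cutoff = report$cutoff, auc = report$auc, band = report$band,
         sensitivity = report$sensitivity, specificity = report$specificity,
         percent_correct = report$percent_correct,
         abstain_rate = report$knn_evaluation$abstain_rate,
         knn_accuracy = report$knn_evaluation$accuracy,
         provenance = report$provenance),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  logistic: AUC %.3f (%s), cutoff %.2f -> sens %.3f spec %.3f, %.1f%% correct\n",
              x$auc, x$band, x$cutoff, x$sensitivity, x$specificity,
              x$percent_correct))
  cat(sprintf("  knn (%s): accuracy %.3f, abstain rate %.3f\n",
              x$provenance$knn_label_scheme,
              x$knn_evaluation$accuracy, x$knn_evaluation$abstain_rate))
  cat(sprintf("  %d specimens aggregated\n", length(x$knn_compositions)))
  invisible(x)
}

#' Side-by-side comparison of two pipeline reports
#'
#' Pairs the headline metrics of two runs over the same cohort with
#' different compartment filters — typically the epithelial-cells-only
#' model against the all-cells model.
#'
#' @param report_a,report_b `pipeline_report`s from [run_pipeline()] with
#'   identical seeds/cohorts.
#' @param labels Character pair naming the two models.
#' @return A tibble: one row per model with `auc`, `band`, `cutoff`,
#'   `sensitivity`, `specificity`, `percent_correct`, `knn_accuracy`,
#'   `n_cells`.
#' @export
compare_models <- function(report_a, report_b,
                           labels = c("epithelial_only", "all_cells")) {
  stopifnot(inherits(report_a, "pipeline_report"),
            inherits(report_b, "pipeline_report"))
  if (!identical(report_a$provenance$seed, report_b$provenance$seed)) {
    stop("reports come from different cohorts (seeds differ)", call. = FALSE)
  }
  row <- function(rp, lb) tibble::tibble(
    model = lb, auc = rp$auc, band = rp$band, cutoff = rp$cutoff,
    sensitivity = rp$sensitivity, specificity = rp$specificity,
    percent_correct = rp$percent_correct,
    knn_accuracy = rp$knn_evaluation$accuracy,
    n_cells = rp$provenance$n_logistic_cells
  )
  rbind(row(report_a, labels[1]), row(report_b, labels[2]))
}
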