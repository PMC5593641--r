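#' Closed vocabularies for per-cell annotation
#'
#' Category tokens used throughout the package for the imaging-frame tissue
#' compartment, the specimen phase, the pathological category and the
#' Gleason group of each imaged nucleus.
#'
#' Compartments span a sampling spectrum from pure epithelium to pure
#' stroma: `E` (epithelium only), `E+s` (epithelium with minor bordering
#' stroma), `ES` (mixed epithelium and stroma), `S` (stroma only). Cultured
#' cells carry a missing (`NA`) compartment. Pathological categories run
#' from benign (`B`) through atypical small acinar proliferation (`ASAP`),
#' adenocarcinoma (`AC`), lots of adenocarcinoma (`LAC`) at biopsy, to
#' `StageII`/`StageIII` at prostatectomy. Gleason groups are benign/no
#' score (`B`), score 6 (3+3) (`G33`), score 7 (3+4) (`G34`) and score 7
#' (4+3) (`G43`).
#'
#' @format Character vectors of allowed tokens. `path_severity` and
#'   `gleason_severity` order the diagnosable classes from least to most
#'   severe and are used for conservative tie-breaking in specimen-level
#'   diagnosis.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
cell_phases <- c("biopsy1", "biopsy2", "prostatectomy", "culture")

#' @rdname vocabularies
#' @export
cell_compartments <- c("E", "E+s", "ES", "S")

#' @rdname vocabularies
#' @export
path_categories <- c("B", "ASAP", "AC", "LAC", "StageII", "StageIII", "unknown")

#' @rdname vocabularies
#' @export
gleason_groups <- c("B", "G33", "G34", "G43", "unknown")

#' @rdname vocabularies
#' @export
path_severity <- c("B", "ASAP", "AC", "LAC", "StageII", "StageIII")

#' @rdname vocabularies
#' @export
gleason_severity <- c("B", "G33", "G34", "G43")

annotation_columns <- c(
  "cell_id", "patient_id", "phase", "frame_id", "compartment",
  "path_category", "gleason_group"
)

#' Construct a per-cell intensity table
#'
#' A `cell_table` is a data frame with one row per imaged nucleus: identity
#' columns (`cell_id`, `patient_id`, `phase`, `frame_id`), annotation
#' columns (`compartment`, `path_category`, `gleason_group`) and one
#' numeric column per marker holding nonnegative nuclear intensities on a
#' 12-bit fluorescence scale (or their natural logs after
#' [log_transform()]). The marker set and a free-form provenance list ride
#' along as attributes.
#'
#' @param df Data frame containing the annotation columns and all `markers`.
#' @param markers Character vector of marker column names (ordered).
#' @param provenance Named list of free-form metadata (source, seed,
#'   filters, transforms applied).
#' @return A `cell_table` (also a `data.frame`).
#' @export
cell_table <- function(df, markers, provenance = list()) {
  df <- as.data.frame(df, check.names = FALSE)
  missing_cols <- setdiff(c(annotation_columns, markers), names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, c(annotation_columns, markers, setdiff(names(df), c(annotation_columns, markers))), drop = FALSE]
  validate_cell_table_values(df, markers,
                             allow_log = isTRUE(provenance$log_transformed))
  key <- paste(df$patient_id, df$phase, df$cell_id)
  if (anyDuplicated(key)) {
    stop("duplicate (patient_id, phase, cell_id) records", call. = FALSE)
  }
  structure(df,
            markers = as.character(markers),
            provenance = provenance,
            class = c("cell_table", "data.frame"))
}

validate_cell_table_values <- function(df, markers, allow_log = FALSE) {
  check_vocab <- function(col, vocab, allow_na = FALSE) {
    vals <- df[[col]]
    bad <- !(vals %in% vocab) & !(allow_na & is.na(vals))
    if (any(bad)) {
      stop(sprintf("unknown %s token '%s' at row %d", col,
                   vals[which(bad)[1]], which(bad)[1]), call. = FALSE)
    }
  }
  check_vocab("phase", cell_phases)
  check_vocab("compartment", cell_compartments, allow_na = TRUE)
  check_vocab("path_category", path_categories)
  check_vocab("gleason_group", gleason_groups)
  for (m in markers) {
    v <- df[[m]]
    if (!is.numeric(v)) stop("marker column '", m, "' is not numeric", call. = FALSE)
    if (anyNA(v)) stop("marker column '", m, "' has missing values", call. = FALSE)
    if (!allow_log && any(v < 0)) {
      stop(sprintf("negative intensity in column '%s' at row %d", m,
                   which(v < 0)[1]), call. = FALSE)
    }
  }
  invisible(df)
}

#' @export
print.cell_table <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("<cell_table> %d cells x %d markers (%s)\n",
              nrow(x), length(attr(x, "markers")),
              paste(attr(x, "markers"), collapse = ", ")))
  if (isTRUE(prov$log_transformed)) cat("  intensities: natural-log scale\n")
  print(tibble::as_tibble(as.data.frame(x)), ...)
  invisible(x)
}

#' @rdname cell_table
#' @param table A `cell_table`.
#' @export
markers <- function(table) attr(table, "markers")

#' @rdname cell_table
#' @export
provenance <- function(table) attr(table, "provenance")

# Rebuild the class/attributes after a row subset.
rebuild <- function(df, template, extra_prov = NULL) {
  prov <- attr(template, "provenance")
  if (!is.null(extra_prov)) prov <- utils::modifyList(prov, extra_prov)
  structure(as.data.frame(df, check.names = FALSE),
            markers = attr(template, "markers"),
            provenance = prov,
            class = c("cell_table", "data.frame"))
}

#' Read / write the cell-table CSV dialect
#'
#' The on-disk dialect is UTF-8 comma-separated text with a header row and
#' "." decimals: the seven annotation columns first, then one column per
#' marker. `write_cell_table()` also writes a JSON provenance sidecar at
#' `<path>.json`; `read_cell_table()` restores it when present. Doubles are
#' written with 17 significant digits, so write-then-read is value-exact.
#'
#' @param path CSV file path.
#' @param markers Marker columns to expect; default: every non-annotation
#'   column in file order.
#' @return `read_cell_table()` a `cell_table`; `write_cell_table()` the
#'   input, invisibly.
#' @export
read_cell_table <- function(path, markers = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, na.strings = "NA",
                        stringsAsFactors = FALSE)
  missing_cols <- setdiff(annotation_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in annotation_columns) df[[col]] <- as.character(df[[col]])
  prov <- list(source = path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    prov <- jsonlite::fromJSON(sidecar, simplifyVector = TRUE)
  }
  if (is.null(markers)) {
    markers <- if (!is.null(prov$markers)) prov$markers else
      setdiff(names(df), c(annotation_columns, "clipped"))
  }
  log_scale <- isTRUE(prov$log_transformed)
  df2 <- validate_cell_table_values(df, markers, allow_log = log_scale)
  extra <- setdiff(names(df2), c(annotation_columns, markers))
  structure(df2[, c(annotation_columns, markers, extra), drop = FALSE],
            markers = as.character(markers),
            provenance = prov,
            class = c("cell_table", "data.frame"))
}

#' @rdname read_cell_table
#' @param table A `cell_table` to write.
#' @export
write_cell_table <- function(table, path) {
  stopifnot(inherits(table, "cell_table"))
  df <- as.data.frame(table, check.names = FALSE)
  # shortest exact decimal representation so write -> read is lossless
  for (col in names(df)) {
    if (is.double(df[[col]])) {
      df[[col]] <- formatC(df[[col]], format = "g", digits = 17)
    }
  }
  utils::write.csv(df, path, na = "NA", row.names = FALSE)
  prov <- provenance(table)
  prov$markers <- markers(table)
  jsonlite::write_json(prov, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(table)
}

#' Natural-log transform of marker intensities
#'
#' Channel intensities are strongly right-skewed, so every downstream model
#' works on the natural-log scale. Each intensity `v` is replaced by
#' `ln(max(v, floor))`; the positive floor clamps zero-valued voxels
#' (rather than dropping the cell, which would distort composition counts),
#' and clamped cells are flagged in the provenance.
#'
#' @param table A `cell_table` on the raw intensity scale.
#' @param floor Positive clamp applied before taking logs (intensity units;
#'   default 1 on the 12-bit scale).
#' @return A `cell_table` with log-scale marker columns and
#'   `log_transformed = TRUE` recorded in the provenance.
#' @export
log_transform <- function(table, floor = 1) {
  stopifnot(inherits(table, "cell_table"))
  if (!is.numeric(floor) || length(floor) != 1 || floor <= 0) {
    stop("floor must be a single positive intensity", call. = FALSE)
  }
  if (isTRUE(provenance(table)$log_transformed)) {
    stop("table is already log-transformed", call. = FALSE)
  }
  mk <- markers(table)
  clamped <- rep(FALSE, nrow(table))
  for (m in mk) {
    v <- table[[m]]
    clamped <- clamped | (v < floor)
    table[[m]] <- log(pmax(v, floor))
  }
  rebuild(table, table,
          extra_prov = list(log_transformed = TRUE, log_floor = floor,
                            n_clamped = sum(clamped)))
}

#' Partition a cohort into development and validation sets by patient
#'
#' Models are developed on one group of patients and validated on held-out
#' patients (and cultured control cells); the split is by `patient_id`, so
#' no cell can appear on both sides.
#'
#' @param table A `cell_table`.
#' @param development_patients,validation_patients Disjoint character
#'   vectors of patient ids.
#' @return A list with `cell_table` elements `development` and `validation`.
#' @export
split_development_validation <- function(table, development_patients,
                                         validation_patients) {
  stopifnot(inherits(table, "cell_table"))
  if (length(intersect(development_patients, validation_patients)) > 0) {
    stop("development and validation patient sets overlap", call. = FALSE)
  }
  dev <- table[table$patient_id %in% development_patients, , drop = FALSE]
  val <- table[table$patient_id %in% validation_patients, , drop = FALSE]
  list(
    development = rebuild(dev, table, list(split = "development")),
    validation = rebuild(val, table, list(split = "validation"))
  )
}

#' Filter cells by imaging-frame tissue compartment
#'
#' Retains only cells whose frame compartment is in `compartments`,
#' preserving row order. Cultured cells carry a missing compartment and are
#' excluded unless `NA` is included explicitly, e.g.
#' `filter_compartment(x, c("E", NA))`.
#'
#' @param table A `cell_table`.
#' @param compartments Subset of [cell_compartments] (optionally with `NA`).
#' @return A filtered `cell_table`.
#' @export
filter_compartment <- function(table, compartments) {
  stopifnot(inherits(table, "cell_table"))
  if (length(compartments) == 0) {
    stop("empty compartment selection", call. = FALSE)
  }
  unknown <- setdiff(compartments[!is.na(compartments)], cell_compartments)
  if (length(unknown) > 0) {
    stop("unknown compartment token(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  keep <- table$compartment %in% compartments
  rebuild(table[keep, , drop = FALSE], table,
          list(compartment_filter = paste(compartments, collapse = ",")))
}
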