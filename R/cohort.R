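#' Cohort tables
#'
#' A cohort is a tibble with a `patient_id` character column followed by one
#' numeric column per schema feature, in schema order, in clinical units.
#' Missing measurements are `NA` and are excluded from every statistic until
#' imputation.  Label tables carry `patient_id` plus the three subtype
#' severities `lv` (logopenic variant), `pca` (posterior cortical atrophy)
#' and `fv` (frontal variant), each in \[0, 1\].
#'
#' @name ad_cohort
NULL

#' Validate a cohort table against a schema
#'
#' Checks column presence, schema ordering and numeric types; reorders
#' columns to schema order if needed.
#'
#' @param cohort Tibble with `patient_id` plus feature columns.
#' @param schema An `ad_schema`.
#' @return The cohort, column-ordered to the schema, invisibly valid.
#' @export
validate_cohort <- function(cohort, schema) {
  validate_schema(schema)
  if (!"patient_id" %in% names(cohort)) {
    abort("Cohort must have a `patient_id` column.")
  }
  missing_cols <- setdiff(schema$name, names(cohort))
  if (length(missing_cols)) {
    abort(paste0("Cohort is missing feature column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(names(cohort), c("patient_id", schema$name))
  if (length(extra)) {
    abort(paste0("Cohort has column(s) not in the schema: ",
                 paste(extra, collapse = ", ")))
  }
  if (anyDuplicated(cohort$patient_id)) {
    abort("Duplicate patient_id values in cohort.")
  }
  cohort <- cohort[, c("patient_id", schema$name)]
  cohort$patient_id <- as.character(cohort$patient_id)
  tibble::as_tibble(cohort)
}

#' Read a cohort CSV
#'
#' The file must have a header naming `patient_id` and every schema feature
#' (any column order); empty cells denote missing values.  Columns are
#' reordered to schema order on read.  A non-numeric entry in a feature
#' column is reported with its row and column.
#'
#' @param path CSV path.
#' @param schema An `ad_schema`.
#' @return A cohort tibble.
#' @export
read_cohort <- function(path, schema) {
  if (!file.exists(path)) abort(paste0("Cohort file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  missing_cols <- setdiff(c("patient_id", schema$name), names(raw))
  if (length(missing_cols)) {
    abort(paste0("Cohort file is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::tibble(patient_id = as.character(raw$patient_id))
  for (feat in schema$name) {
    cell <- raw[[feat]]
    cell[cell == ""] <- NA_character_
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(val))
    if (length(bad)) {
      abort(sprintf(
        "Non-numeric value %s in column '%s', row %d of %s",
        dQuote(cell[bad[1]]), feat, bad[1], path
      ))
    }
    out[[feat]] <- val
  }
  validate_cohort(out, schema)
}

#' Write a cohort CSV
#'
#' Missing entries are written as empty cells; `read_cohort()` of the result
#' reproduces values, missingness and patient ids exactly.
#'
#' @param cohort Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- dplyr::mutate(cohort, dplyr::across(dplyr::where(is.numeric),
                                             format_roundtrip))
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read / write subtype-severity label tables
#'
#' Label files are CSV with columns `patient_id, lv, pca, fv`; severities
#' must lie in \[0, 1\].
#'
#' @param path CSV path.
#' @return `read_labels()`: a label tibble.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) abort(paste0("Label file not found: ", path))
  lab <- readr::read_csv(path,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(c("patient_id", "lv", "pca", "fv"), names(lab))
  if (length(missing_cols)) {
    abort(paste0("Label file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  # parse through as.numeric: correctly rounded, so files round-trip exactly
  lab <- tibble::tibble(
    patient_id = lab$patient_id,
    lv = as.numeric(lab$lv), pca = as.numeric(lab$pca), fv = as.numeric(lab$fv)
  )
  validate_labels(lab)
  lab
}

#' @rdname read_labels
#' @param labels Label tibble with columns `patient_id, lv, pca, fv`.
#' @export
write_labels <- function(labels, path) {
  validate_labels(labels)
  out <- dplyr::mutate(labels, dplyr::across(dplyr::where(is.numeric),
                                             format_roundtrip))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

validate_labels <- function(labels) {
  req <- c("patient_id", "lv", "pca", "fv")
  missing_cols <- setdiff(req, names(labels))
  if (length(missing_cols)) {
    abort(paste0("Label table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (s in c("lv", "pca", "fv")) check_prob(labels[[s]], s)
  invisible(labels)
}

# numeric matrix of feature values (patients x features), schema order
cohort_matrix <- function(cohort, schema) {
  m <- as.matrix(cohort[, schema$name])
  storage.mode(m) <- "double"
  rownames(m) <- cohort$patient_id
  m
}
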