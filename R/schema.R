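#' Feature schemas
#'
#' A feature schema is an ordered tibble describing every clinical variable a
#' cohort table may contain: its `name`, `category` (demographic,
#' blood_chemistry, biochemical, endocrine_immune, neurological, lifestyle),
#' the processing `group` it is routed to inside the model (`G1_blood`,
#' `G2_biochem`, `G3_endocrine`, `G4_lifestyle`, or `DIRECT` for markers fed
#' straight into the trunk), its `value_kind` (continuous, binary, ordinal),
#' and an optional clinical reference range (`ref_low`, `ref_high`) used by
#' reference-range min-max normalization.
#'
#' @name ad_schema
NULL

ad_categories <- c(
  "demographic", "blood_chemistry", "biochemical",
  "endocrine_immune", "neurological", "lifestyle"
)
ad_group_names <- c("G1_blood", "G2_biochem", "G3_endocrine", "G4_lifestyle")
ad_value_kinds <- c("continuous", "binary", "ordinal")

new_ad_schema <- function(df) {
  df <- tibble::as_tibble(df)
  class(df) <- c("ad_schema", class(df))
  df
}

validate_schema <- function(schema) {
  req <- c("name", "category", "group", "value_kind", "ref_low", "ref_high")
  missing_cols <- setdiff(req, names(schema))
  if (length(missing_cols)) {
    abort(paste0("Schema is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  dup <- schema$name[duplicated(schema$name)]
  if (length(dup)) {
    abort(paste0("Duplicate feature name(s) in schema: ", paste(unique(dup), collapse = ", ")))
  }
  bad_group <- setdiff(unique(schema$group), c(ad_group_names, "DIRECT"))
  if (length(bad_group)) {
    abort(paste0("Unknown processing group(s): ", paste(bad_group, collapse = ", ")))
  }
  bad_cat <- setdiff(unique(schema$category), ad_categories)
  if (length(bad_cat)) {
    abort(paste0("Unknown category(s): ", paste(bad_cat, collapse = ", ")))
  }
  bad_kind <- setdiff(unique(schema$value_kind), ad_value_kinds)
  if (length(bad_kind)) {
    abort(paste0("Unknown value_kind(s): ", paste(bad_kind, collapse = ", ")))
  }
  neuro_off <- schema$name[schema$category == "neurological" & schema$group != "DIRECT"]
  if (length(neuro_off)) {
    abort(paste0(
      "Neurological markers must be DIRECT features: ",
      paste(neuro_off, collapse = ", ")
    ))
  }
  has_range <- !is.na(schema$ref_low) & !is.na(schema$ref_high)
  bad_range <- schema$name[has_range & !(schema$ref_low < schema$ref_high)]
  if (length(bad_range)) {
    abort(paste0(
      "Reference range must satisfy low < high for: ",
      paste(bad_range, collapse = ", ")
    ))
  }
  invisible(schema)
}

#' Read a feature schema from a YAML config
#'
#' The config holds a `features:` list; each entry gives `name`, `category`,
#' `group`, `value_kind`, and optionally `reference_range: [low, high]`.
#'
#' @param path Path to the YAML schema file.
#' @return An `ad_schema` tibble.
#' @seealso [default_schema()], [write_schema()]
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) abort(paste0("Schema file not found: ", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$features)) abort("Schema config must contain a `features` list.")
  rows <- purrr::map(cfg$features, function(f) {
    rng <- f$reference_range
    tibble::tibble(
      name = as.character(f$name),
      category = as.character(f$category),
      group = as.character(f$group),
      value_kind = as.character(f$value_kind),
      ref_low = if (is.null(rng)) NA_real_ else as.numeric(rng[[1]]),
      ref_high = if (is.null(rng)) NA_real_ else as.numeric(rng[[2]])
    )
  })
  schema <- new_ad_schema(dplyr::bind_rows(rows))
  validate_schema(schema)
  schema
}

#' Write a feature schema to a YAML config
#'
#' @param schema An `ad_schema` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  validate_schema(schema)
  feats <- purrr::pmap(schema, function(name, category, group, value_kind,
                                        ref_low, ref_high, ...) {
    f <- list(name = name, category = category, group = group,
              value_kind = value_kind)
    if (!is.na(ref_low) && !is.na(ref_high)) {
      f$reference_range <- c(ref_low, ref_high)
    }
    f
  })
  yaml::write_yaml(list(features = feats), path)
  invisible(path)
}

#' The bundled default feature schema
#'
#' The full clinical variable list the model was designed around: 16
#' haematology features (G1_blood), 34 clinical-chemistry features
#' (G2_biochem), 17 endocrine/immunological features (G3_endocrine), 12
#' lifestyle/demographic features (G4_lifestyle), and the two DIRECT
#' neurological markers B2MG (beta2-microglobulin, reference range 1–3 mg/L)
#' and MMSE.
#'
#' @return An `ad_schema` tibble with 81 features.
#' @examples
#' sch <- default_schema()
#' table(sch$group)
#' @export
default_schema <- function() {
  path <- system.file("extdata", "default_schema.yaml", package = "adattn")
  read_schema(path)
}

#' Group membership of a schema
#'
#' @param schema An `ad_schema`.
#' @return Named list mapping each non-DIRECT group present in the schema to
#'   its ordered feature names.
#' @export
schema_groups <- function(schema) {
  g <- schema$group[schema$group != "DIRECT"]
  split(schema$name[schema$group != "DIRECT"], factor(g, levels = ad_group_names))
}

#' DIRECT (trunk pass-through) features of a schema
#'
#' @param schema An `ad_schema`.
#' @return Character vector of feature names with group `DIRECT`.
#' @export
direct_features <- function(schema) {
  schema$name[schema$group == "DIRECT"]
}
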