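#' Model configuration
#'
#' @param d Token embedding dimension used inside each group's attention
#'   module (default 8).
#' @param hidden Trunk hidden-layer widths (default `c(64, 32)`).
#' @param activation Hidden activation, `"relu"` or `"tanh"`.
#' @param output Output activation: `"sigmoid"` (three independent
#'   severities in \[0, 1\], the default) or `"softmax"` (ablation mode; its
#'   sum-to-1 constraint contradicts independent subtype severities).
#' @param score_scale Attention score scaling: `"sqrt"` divides scores by
#'   `sqrt(d)` (default), `"linear"` divides by `d`.
#' @param seed Integer seed for parameter initialization.
#' @return An `ad_model_config` list.
#' @export
ad_model_config <- function(d = 8L, hidden = c(64L, 32L),
                            activation = c("relu", "tanh"),
                            output = c("sigmoid", "softmax"),
                            score_scale = c("sqrt", "linear"),
                            seed = 1L) {
  if (d < 1L) abort("`d` must be a positive integer.")
  if (length(hidden) < 1L || any(hidden < 1L)) {
    abort("`hidden` must be positive layer widths.")
  }
  structure(list(
    d = as.integer(d), hidden = as.integer(hidden),
    activation = match.arg(activation), output = match.arg(output),
    score_scale = match.arg(score_scale), seed = as.integer(seed)
  ), class = "ad_model_config")
}

#' Build the grouped-attention model
#'
#' Constructs the modular architecture: each of the four feature groups gets
#' per-feature token embeddings processed by scaled dot-product
#' self-attention and mean-pooled to a `d`-vector; the four context vectors
#' are concatenated with the DIRECT features (e.g. B2MG, MMSE) into a trunk
#' of fully connected layers ending in three severity outputs.
#'
#' @param schema An `ad_schema` whose four processing groups are all
#'   non-empty.
#' @param config An [ad_model_config()].
#' @return An `ad_model` of kind `"modular"` with seeded initial parameters;
#'   trunk input length is `4 * d + (number of DIRECT features)`.
#' @export
build_model <- function(schema, config = ad_model_config()) {
  validate_schema(schema)
  groups <- schema_groups(schema)
  empty <- names(groups)[vapply(groups, length, integer(1)) == 0L]
  if (length(empty)) {
    abort(paste0("Cannot build modular model: empty group(s): ",
                 paste(empty, collapse = ", ")))
  }
  direct <- direct_features(schema)
  d <- config$d
  trunk_in <- length(groups) * d + length(direct)
  params <- withr::with_seed(config$seed, {
    embed_W <- purrr::map(groups, ~ matrix(rnorm(length(.x) * d), length(.x), d))
    embed_B <- purrr::map(groups, ~ matrix(rnorm(length(.x) * d, sd = 0.1), length(.x), d))
    tr <- init_trunk(trunk_in, config$hidden)
    list(embed_W = embed_W, embed_B = embed_B, trunk_W = tr$W, trunk_b = tr$b)
  })
  structure(list(
    kind = "modular",
    schema_names = schema$name,
    groups = groups,
    direct = direct,
    config = config,
    params = params
  ), class = "ad_model")
}

# He-normal trunk initialization; consumes RNG in layer order
init_trunk <- function(input_len, hidden, n_out = 3L) {
  sizes <- c(input_len, hidden, n_out)
  W <- list()
  b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    fan_in <- sizes[l]
    W[[l]] <- matrix(rnorm(fan_in * sizes[l + 1L], sd = sqrt(2 / fan_in)),
                     fan_in, sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(W = W, b = b)
}

#' Count trainable parameters
#'
#' @param model An `ad_model`.
#' @return Integer count of trainable scalars.
#' @export
count_parameters <- function(model) {
  sum(vapply(unlist(model$params, recursive = FALSE), length, integer(1)))
}

#' Build a parameter-matched fully connected baseline
#'
#' A plain multilayer perceptron over the full concatenated normalized
#' feature vector, with the same depth class as the modular model (input,
#' hidden layers, three outputs) and hidden widths solved by integer search
#' so its trainable parameter count lies within ±10\% of the modular
#' model's.
#'
#' @param schema An `ad_schema`.
#' @param config An [ad_model_config()]; `hidden` fixes the width *ratios*
#'   of the baseline's hidden layers.
#' @param tolerance Maximum allowed relative parameter-count mismatch
#'   (default 0.10).
#' @return An `ad_model` of kind `"mlp"`; its `parity` field records both
#'   parameter counts and their relative difference.
#' @export
build_matched_baseline <- function(schema, config = ad_model_config(),
                                   tolerance = 0.10) {
  proposed <- build_model(schema, config)
  target <- count_parameters(proposed)
  n_in <- length(schema$name)
  ratios <- config$hidden / config$hidden[1]
  n_params_for <- function(h1) {
    sizes <- c(n_in, pmax(1L, as.integer(round(h1 * ratios))), 3L)
    sum(sizes[-length(sizes)] * sizes[-1] + sizes[-1])
  }
  h_max <- max(64L, as.integer(ceiling(target / max(n_in, 1L))) + 64L)
  counts <- vapply(seq_len(h_max), n_params_for, numeric(1))
  best <- which.min(abs(counts - target))
  rel <- abs(counts[best] - target) / target
  if (rel > tolerance) {
    abort(sprintf(
      paste0("Cannot parameter-match baseline within %.0f%% at this depth; ",
             "closest width %d gives %d vs %d parameters. ",
             "Try widths in [%d, %d] or another depth."),
      100 * tolerance, best, counts[best], target, 1L, h_max))
  }
  hidden <- pmax(1L, as.integer(round(best * ratios)))
  params <- withr::with_seed(config$seed, {
    tr <- init_trunk(n_in, hidden)
    list(trunk_W = tr$W, trunk_b = tr$b)
  })
  structure(list(
    kind = "mlp",
    schema_names = schema$name,
    groups = NULL,
    direct = NULL,
    config = modifyList(unclass(config), list(hidden = hidden)),
    params = params,
    parity = list(proposed = target, baseline = as.integer(counts[best]),
                  relative_diff = rel)
  ), class = "ad_model")
}

# cohort -> list(Vg = per-group matrices, direct = matrix, X = full matrix)
model_matrices <- function(model, cohort) {
  feats <- model$schema_names
  missing_cols <- setdiff(feats, names(cohort))
  if (length(missing_cols)) {
    abort(paste0("Cohort is missing feature column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  X <- as.matrix(cohort[, feats])
  storage.mode(X) <- "double"
  if (anyNA(X)) abort("Model inputs contain missing values; impute first.")
  if (any(X < -1e-9 | X > 1 + 1e-9)) {
    abort("Model inputs must be normalized to [0, 1].")
  }
  X[] <- pmin(1, pmax(0, X))
  if (model$kind == "mlp") return(list(X = X))
  list(
    Vg = purrr::map(model$groups, ~ X[, .x, drop = FALSE]),
    direct = X[, model$direct, drop = FALSE]
  )
}

model_forward_matrix <- function(model, mats) {
  cfg <- model$config
  if (model$kind == "modular") {
    cpp_modular_forward(
      unname(mats$Vg), mats$direct,
      unname(model$params$embed_W), unname(model$params$embed_B),
      model$params$trunk_W, model$params$trunk_b,
      cfg$activation, cfg$output, cfg$score_scale
    )$probs
  } else {
    cpp_mlp_forward(mats$X, model$params$trunk_W, model$params$trunk_b,
                    cfg$activation, cfg$output)
  }
}

#' Run the model forward on a normalized cohort
#'
#' @param model An `ad_model`.
#' @param cohort Preprocessed cohort tibble: imputed and min-max normalized,
#'   every feature value in \[0, 1\].
#' @return Label tibble `patient_id, lv, pca, fv` of predicted subtype
#'   severities, each in \[0, 1\].
#' @export
forward <- function(model, cohort) {
  mats <- model_matrices(model, cohort)
  P <- model_forward_matrix(model, mats)
  tibble::tibble(
    patient_id = as.character(cohort$patient_id),
    lv = P[, 1], pca = P[, 2], fv = P[, 3]
  )
}

#' @export
predict.ad_model <- function(object, newdata, ...) {
  forward(object, newdata)
}

#' @export
print.ad_model <- function(x, ...) {
  cat(sprintf(
    "<ad_model: %s>\n  features: %d\n  parameters: %d\n",
    if (x$kind == "modular") "grouped-attention model" else "fully connected baseline",
    length(x$schema_names), count_parameters(x)
  ))
  if (x$kind == "modular") {
    cat(sprintf("  groups: %s | DIRECT: %s\n",
                paste(sprintf("%s(%d)", names(x$groups),
                              vapply(x$groups, length, integer(1))),
                      collapse = ", "),
                paste(x$direct, collapse = ", ")))
  }
  invisible(x)
}

#' Extract per-patient attention weights for interpretability
#'
#' Recomputes the row-stochastic attention matrices of one group for every
#' patient and returns them in long (tidy) form, ready for heatmap plotting
#' or CSV export.
#'
#' @param model A modular `ad_model`.
#' @param cohort Normalized cohort tibble.
#' @param group Group name (e.g. `"G2_biochem"`); default all groups.
#' @return Tibble `patient_id, group, from, to, weight`; within each
#'   patient/group/from, weights sum to 1.
#' @export
attention_weights <- function(model, cohort, group = NULL) {
  if (model$kind != "modular") abort("Attention weights exist only for the modular model.")
  mats <- model_matrices(model, cohort)
  groups <- group %||% names(model$groups)
  purrr::map_dfr(groups, function(g) {
    feats <- model$groups[[g]]
    cube <- cpp_attention_weights(
      mats$Vg[[g]], model$params$embed_W[[g]], model$params$embed_B[[g]],
      model$config$score_scale
    )
    n <- length(feats)
    m <- dim(cube)[3]
    tibble::tibble(
      patient_id = rep(as.character(cohort$patient_id), each = n * n),
      group = g,
      from = rep(rep(feats, times = n), times = m),
      to = rep(rep(feats, each = n), times = m),
      weight = as.vector(cube)
    )
  })
}

#' Serialize a model to structured text (JSON)
#'
#' Stores architecture metadata and flat weight arrays with full numeric
#' precision; [read_model()] restores a working model.
#'
#' @param model An `ad_model` (or an `ad_fit`, whose trained model is saved).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "ad_fit")) model <- model$model
  payload <- list(
    kind = model$kind,
    schema_names = model$schema_names,
    groups = model$groups,
    direct = model$direct,
    config = unclass(model$config),
    parity = model$parity,
    params = purrr::map(model$params, function(part) {
      purrr::map(part, function(w) {
        list(dim = dim(w) %||% length(w), values = as.vector(w))
      })
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  params <- purrr::map(p$params, function(part) {
    purrr::map(part, function(w) {
      v <- as.numeric(w$values)
      if (length(w$dim) == 2L) dim(v) <- w$dim
      v
    })
  })
  cfg <- p$config
  config <- ad_model_config(d = cfg$d, hidden = cfg$hidden,
                            activation = cfg$activation, output = cfg$output,
                            score_scale = cfg$score_scale, seed = cfg$seed)
  if (p$kind == "mlp") config <- modifyList(unclass(config), list(hidden = cfg$hidden))
  structure(list(
    kind = p$kind,
    schema_names = p$schema_names,
    groups = if (p$kind == "modular") as.list(p$groups) else NULL,
    direct = p$direct,
    config = config,
    params = params,
    parity = p$parity
  ), class = "ad_model")
}
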