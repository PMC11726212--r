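#' Preprocessing: imputation, normalization, splitting, oversampling
#'
#' The pipeline order is fixed: fit mean imputation and min-max bounds on the
#' training split only, apply them everywhere, then oversample the training
#' set with SMOTE.  [preprocess_cohort()] enforces that order; SMOTE can
#' never touch validation or test data through the public API.
#'
#' @name ad_preprocess
NULL

#' Fit per-feature training means for mean imputation
#'
#' @param cohort Training cohort tibble (clinical units, `NA` = missing).
#' @param schema An `ad_schema`.
#' @return An `ad_imputer`: tibble with columns `feature`, `mean`.
#' @export
fit_imputer <- function(cohort, schema) {
  cohort <- validate_cohort(cohort, schema)
  mu <- vapply(schema$name, function(f) mean(cohort[[f]], na.rm = TRUE), numeric(1))
  bad <- schema$name[!is.finite(mu)]
  if (length(bad)) {
    abort(paste0("Cannot fit imputer: feature(s) with no observed values: ",
                 paste(bad, collapse = ", ")))
  }
  out <- tibble::tibble(feature = schema$name, mean = unname(mu))
  class(out) <- c("ad_imputer", class(out))
  out
}

#' Replace missing entries by fitted feature means
#'
#' Observed entries are left untouched; the result has no missing values.
#'
#' @param cohort Cohort tibble.
#' @param imputer An `ad_imputer` from [fit_imputer()].
#' @return Cohort tibble with `NA`s replaced.
#' @export
apply_imputer <- function(cohort, imputer) {
  missing_feats <- setdiff(setdiff(names(cohort), "patient_id"), imputer$feature)
  if (length(missing_feats)) {
    abort(paste0("Imputer has no mean for feature(s): ",
                 paste(missing_feats, collapse = ", ")))
  }
  for (i in seq_len(nrow(imputer))) {
    f <- imputer$feature[i]
    if (f %in% names(cohort)) {
      cohort[[f]][is.na(cohort[[f]])] <- imputer$mean[i]
    }
  }
  cohort
}

#' Fit min-max normalization bounds
#'
#' Uses the schema's clinical reference range where present (e.g. 1–3 mg/L
#' for B2MG, so 1 maps to 0 and 3 maps to 1) and the observed training
#' min/max otherwise.
#'
#' @param cohort Training cohort (imputed or not; `NA`s are ignored).
#' @param schema An `ad_schema`.
#' @return An `ad_normalizer`: tibble with columns `feature`, `low`, `high`.
#' @export
fit_normalizer <- function(cohort, schema) {
  cohort <- validate_cohort(cohort, schema)
  low <- schema$ref_low
  high <- schema$ref_high
  for (i in seq_len(nrow(schema))) {
    if (is.na(low[i]) || is.na(high[i])) {
      x <- cohort[[schema$name[i]]]
      low[i] <- suppressWarnings(min(x, na.rm = TRUE))
      high[i] <- suppressWarnings(max(x, na.rm = TRUE))
    }
  }
  bad <- schema$name[!is.finite(low) | !is.finite(high) | !(low < high)]
  if (length(bad)) {
    abort(paste0("Degenerate normalization bounds (low >= high) for: ",
                 paste(bad, collapse = ", ")))
  }
  out <- tibble::tibble(feature = schema$name, low = low, high = high)
  class(out) <- c("ad_normalizer", class(out))
  out
}

#' Min-max normalize a cohort to the unit interval
#'
#' Applies `x -> (x - low) / (high - low)` per feature, then clips to
#' \[0, 1\] so out-of-range clinical values cannot leave the model's input
#' domain.  The cohort must already be imputed (no missing entries).
#'
#' @param cohort Imputed cohort tibble.
#' @param normalizer An `ad_normalizer` from [fit_normalizer()].
#' @return Cohort tibble with all feature values in \[0, 1\].
#' @export
normalize_cohort <- function(cohort, normalizer) {
  feats <- setdiff(names(cohort), "patient_id")
  missing_feats <- setdiff(feats, normalizer$feature)
  if (length(missing_feats)) {
    abort(paste0("Normalizer has no bounds for feature(s): ",
                 paste(missing_feats, collapse = ", ")))
  }
  if (anyNA(cohort[, feats])) {
    abort("Cohort has missing values; impute before normalizing.")
  }
  for (i in seq_len(nrow(normalizer))) {
    f <- normalizer$feature[i]
    if (f %in% feats) {
      z <- (cohort[[f]] - normalizer$low[i]) / (normalizer$high[i] - normalizer$low[i])
      cohort[[f]] <- pmin(1, pmax(0, z))
    }
  }
  cohort
}

#' Split a cohort into train / validation / test
#'
#' Sizes follow largest-remainder rounding of the fractions in the fixed
#' order (train, validation, test); remainder ties go to the earlier split.
#' Assignment is a seeded uniform permutation, so the same seed always
#' yields the same partition.
#'
#' @param cohort Cohort tibble.
#' @param labels Label tibble aligned by `patient_id`.
#' @param prop Length-3 positive fractions summing to 1
#'   (default `c(0.70, 0.15, 0.15)`).
#' @param seed Integer seed.
#' @return Named list `train`, `val`, `test`; each element is a list with
#'   `cohort` and `labels` tibbles.
#' @export
split_cohort <- function(cohort, labels, prop = c(0.70, 0.15, 0.15), seed = 1L) {
  if (length(prop) != 3L || any(prop <= 0) || abs(sum(prop) - 1) > 1e-8) {
    abort("`prop` must be three positive fractions summing to 1.")
  }
  n <- nrow(cohort)
  if (n < 3L) abort("Need at least 3 patients to split.")
  if (!setequal(cohort$patient_id, labels$patient_id)) {
    abort("Cohort and label patient ids do not match.")
  }
  labels <- labels[match(cohort$patient_id, labels$patient_id), ]
  sizes <- largest_remainder(n, prop)
  idx <- withr::with_seed(seed, sample.int(n))
  cut_points <- cumsum(sizes)
  parts <- list(
    train = idx[seq_len(sizes[1])],
    val = idx[seq.int(cut_points[1] + 1L, length.out = sizes[2])],
    test = idx[seq.int(cut_points[2] + 1L, length.out = sizes[3])]
  )
  purrr::map(parts, function(i) {
    i <- sort(i)
    list(cohort = cohort[i, ], labels = labels[i, ])
  })
}

# largest-remainder apportionment; ties broken toward the earlier entry
largest_remainder <- function(n, prop) {
  quota <- n * prop
  sizes <- floor(quota)
  rem <- quota - sizes
  leftover <- n - sum(sizes)
  if (leftover > 0) {
    take <- order(-rem, seq_along(rem))[seq_len(leftover)]
    sizes[take] <- sizes[take] + 1L
  }
  as.integer(sizes)
}

#' SMOTE minority oversampling
#'
#' Equalizes stratum counts to the majority stratum by interpolation: each
#' synthetic point is `x + u * (z - x)` with `u ~ Uniform(0, 1)` and `z` one
#' of `x`'s `k` nearest same-stratum neighbours under Euclidean distance.
#' Original rows are preserved verbatim.  The parent indices and `u` draws
#' of the synthetic rows are returned so callers can interpolate aligned
#' label vectors identically.
#'
#' @param x Numeric matrix or data frame of fully numeric features.
#' @param strata Vector of stratum keys, one per row.
#' @param k Number of nearest neighbours (capped at stratum size − 1).
#' @param seed Integer seed.
#' @return List with `x` (augmented matrix), `strata` (augmented keys), and
#'   `synthetic`: tibble of `parent`, `neighbor`, `u`, `stratum` describing
#'   each synthetic row in order.
#' @export
smote <- function(x, strata, k = 5L, seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) abort("SMOTE requires fully numeric features without missing values.")
  if (nrow(x) != length(strata)) abort("`strata` must have one entry per row of `x`.")
  if (k < 1L) abort("`k` must be at least 1.")
  counts <- table(strata)
  if (any(counts == 1L)) {
    abort(paste0("Stratum of size 1 has no neighbour to interpolate with: ",
                 paste(names(counts)[counts == 1L], collapse = ", ")))
  }
  target <- max(counts)
  syn_rows <- list()
  syn_meta <- list()
  withr::with_seed(seed, {
    for (s in names(counts)) {
      need <- target - counts[[s]]
      if (need == 0L) next
      idx <- which(strata == s)
      xs <- x[idx, , drop = FALSE]
      d <- as.matrix(stats::dist(xs))
      diag(d) <- Inf
      kk <- min(k, length(idx) - 1L)
      nn <- apply(d, 1L, function(row) order(row)[seq_len(kk)])
      nn <- matrix(nn, nrow = kk)  # kk x |stratum|
      parent_local <- sample.int(length(idx), need, replace = TRUE)
      nb_pick <- sample.int(kk, need, replace = TRUE)
      neighbor_local <- nn[cbind(nb_pick, parent_local)]
      u <- runif(need)
      p <- xs[parent_local, , drop = FALSE]
      q <- xs[neighbor_local, , drop = FALSE]
      syn_rows[[s]] <- p + u * (q - p)
      syn_meta[[s]] <- tibble::tibble(
        parent = idx[parent_local],
        neighbor = idx[neighbor_local],
        u = u,
        stratum = s
      )
    }
  })
  if (length(syn_rows)) {
    syn <- do.call(rbind, syn_rows)
    meta <- dplyr::bind_rows(syn_meta)
    list(
      x = rbind(x, syn),
      strata = c(strata, rep(names(syn_rows), vapply(syn_rows, nrow, integer(1)))),
      synthetic = meta
    )
  } else {
    list(x = x, strata = strata,
         synthetic = tibble::tibble(parent = integer(), neighbor = integer(),
                                    u = numeric(), stratum = character()))
  }
}

#' Full leakage-safe preprocessing pipeline
#'
#' Splits the cohort, fits mean imputation and min-max bounds on the
#' training split only, applies them to all three splits, and (optionally)
#' SMOTE-oversamples the training split.  Strata for SMOTE are the triple of
#' binarized subtype presences of the true severities at threshold `tau`;
#' synthetic rows receive labels interpolated with the same `u` as their
#' features.  Strata with fewer than 2 members are left unaugmented with a
#' warning.
#'
#' @param cohort Cohort tibble (clinical units, `NA` = missing).
#' @param labels Label tibble.
#' @param schema An `ad_schema`.
#' @param prop Split fractions (default 70/15/15).
#' @param seed Integer seed driving split and SMOTE.
#' @param use_smote Oversample the training split? (default `TRUE`)
#' @param k SMOTE neighbour count (default 5, capped at stratum size − 1).
#' @param tau Presence threshold defining SMOTE strata (default 0.5).
#' @return List with `train`, `val`, `test` (each `cohort` + `labels`,
#'   normalized to \[0, 1\]), plus the fitted `imputer` and `normalizer`.
#' @export
preprocess_cohort <- function(cohort, labels, schema,
                              prop = c(0.70, 0.15, 0.15), seed = 1L,
                              use_smote = TRUE, k = 5L, tau = 0.5) {
  cohort <- validate_cohort(cohort, schema)
  validate_labels(labels)
  splits <- split_cohort(cohort, labels, prop, seed)
  imputer <- fit_imputer(splits$train$cohort, schema)
  normalizer <- fit_normalizer(apply_imputer(splits$train$cohort, imputer), schema)
  splits <- purrr::map(splits, function(sp) {
    sp$cohort <- normalize_cohort(apply_imputer(sp$cohort, imputer), normalizer)
    sp
  })
  if (use_smote) {
    splits$train <- smote_training_split(splits$train, schema, k, tau, seed)
  }
  c(splits, list(imputer = imputer, normalizer = normalizer))
}

smote_training_split <- function(train, schema, k, tau, seed) {
  lab <- train$labels
  calls <- cbind(lab$lv >= tau, lab$pca >= tau, lab$fv >= tau)
  strata <- apply(calls, 1L, function(b) paste(as.integer(b), collapse = ""))
  counts <- table(strata)
  singletons <- names(counts)[counts < 2L]
  keep <- !(strata %in% singletons)
  if (length(singletons)) {
    warn(paste0("SMOTE skipped singleton stratum(s): ",
                paste(singletons, collapse = ", ")))
  }
  x <- cohort_matrix(train$cohort, schema)
  res <- smote(x[keep, , drop = FALSE], strata[keep], k = k, seed = seed)
  n_orig <- sum(keep)
  n_syn <- nrow(res$synthetic)
  if (n_syn == 0L && all(keep)) return(train)
  lab_kept <- lab[keep, ]
  syn_lab <- NULL
  if (n_syn > 0L) {
    p <- as.matrix(lab_kept[res$synthetic$parent, c("lv", "pca", "fv")])
    q <- as.matrix(lab_kept[res$synthetic$neighbor, c("lv", "pca", "fv")])
    s <- p + res$synthetic$u * (q - p)
    syn_lab <- tibble::tibble(
      patient_id = paste0("SYN", seq_len(n_syn)),
      lv = s[, 1], pca = s[, 2], fv = s[, 3]
    )
  }
  syn_x <- res$x[seq.int(n_orig + 1L, length.out = n_syn), , drop = FALSE]
  syn_cohort <- tibble::as_tibble(as.data.frame(syn_x))
  names(syn_cohort) <- schema$name
  syn_cohort <- dplyr::bind_cols(
    tibble::tibble(patient_id = if (n_syn) paste0("SYN", seq_len(n_syn)) else character()),
    syn_cohort
  )
  list(
    cohort = dplyr::bind_rows(train$cohort[keep, ], train$cohort[!keep, ], syn_cohort),
    labels = dplyr::bind_rows(lab_kept, lab[!keep, ], syn_lab)
  )
}
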