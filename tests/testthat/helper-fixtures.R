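# In-code fixtures shared across the suite.

# Minimal schema: `per_group` features in each of the four groups plus the
# two DIRECT neurological markers, all with unit reference ranges.
tiny_schema <- function(per_group = 2L) {
  rows <- purrr::map_dfr(adattn:::ad_group_names, function(g) {
    cat <- switch(g, G1_blood = "blood_chemistry", G2_biochem = "biochemical",
                  G3_endocrine = "endocrine_immune", G4_lifestyle = "lifestyle")
    tibble::tibble(
      name = paste0(sub("_.*", "", g), "_f", seq_len(per_group)),
      category = cat, group = g, value_kind = "continuous",
      ref_low = 0, ref_high = 1
    )
  })
  rows <- dplyr::bind_rows(rows, tibble::tibble(
    name = c("B2MG", "MMSE"), category = "neurological", group = "DIRECT",
    value_kind = "continuous", ref_low = c(1, 0), ref_high = c(3, 30)
  ))
  adattn:::new_ad_schema(rows)
}

# Random normalized cohort for a schema (values already in [0, 1]).
tiny_cohort <- function(schema, n = 8L, seed = 1L) {
  withr::with_seed(seed, {
    out <- tibble::tibble(patient_id = sprintf("T%03d", seq_len(n)))
    for (f in schema$name) out[[f]] <- runif(n)
    out
  })
}

random_labels <- function(ids, seed = 1L) {
  withr::with_seed(seed, tibble::tibble(
    patient_id = ids, lv = runif(length(ids)), pca = runif(length(ids)),
    fv = runif(length(ids))
  ))
}

# Independent two-loop oracle for scaled dot-product attention.
attention_oracle <- function(X, score_scale = "sqrt") {
  n <- nrow(X); d <- ncol(X)
  scl <- if (score_scale == "sqrt") sqrt(d) else d
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    S[i, j] <- sum(X[i, ] * X[j, ]) / scl
  }
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    e <- exp(S[i, ] - max(S[i, ]))
    W[i, ] <- e / sum(e)
  }
  list(weights = W, context = W %*% X)
}

# Central finite-difference gradient of the training loss w.r.t. the
# flattened parameter vector.
numeric_gradient <- function(model, mats, Y, loss, h = 1e-5) {
  skeleton <- model$params
  theta <- adattn:::flatten_params(skeleton)
  g <- numeric(length(theta))
  for (i in seq_along(theta)) {
    up <- theta; up[i] <- up[i] + h
    dn <- theta; dn[i] <- dn[i] - h
    mu <- model; mu$params <- adattn:::unflatten_params(up, skeleton)
    md <- model; md$params <- adattn:::unflatten_params(dn, skeleton)
    g[i] <- (adattn:::eval_loss(mu, mats, Y, loss) -
             adattn:::eval_loss(md, mats, Y, loss)) / (2 * h)
  }
  g
}
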