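schema <- tiny_schema()

test_that("the modular model wires four attention modules plus DIRECT slots", {
  m <- build_model(default_schema(), ad_model_config(d = 8, seed = 1))
  # trunk input: four pooled d-vectors plus the two DIRECT markers
  expect_equal(nrow(m$params$trunk_W[[1]]), 4 * 8 + 2)
  expect_equal(ncol(m$params$trunk_W[[length(m$params$trunk_W)]]), 3L)

  m2 <- build_model(default_schema(), ad_model_config(d = 8, seed = 1))
  expect_identical(m$params, m2$params)  # bit-identical under the seed

  no_g4 <- default_schema()
  no_g4 <- no_g4[no_g4$group != "G4_lifestyle", ]
  expect_error(build_model(no_g4, ad_model_config()), "G4_lifestyle")
})

test_that("count_parameters counts trainable scalars exactly", {
  lin <- structure(list(params = list(trunk_W = list(matrix(0, 4, 3)),
                                      trunk_b = list(numeric(3)))),
                   class = "ad_model")
  expect_equal(count_parameters(lin), 15L)
  narrow <- build_model(schema, ad_model_config(hidden = c(8, 4), seed = 1))
  wide <- build_model(schema, ad_model_config(hidden = c(16, 8), seed = 1))
  expect_gt(count_parameters(wide), count_parameters(narrow))
})

test_that("the baseline parameter-matches the modular model within 10%", {
  configs <- list(
    ad_model_config(seed = 1),
    ad_model_config(d = 4, seed = 1),
    ad_model_config(hidden = c(32, 16), seed = 1),
    ad_model_config(d = 12, hidden = c(48, 24), seed = 1)
  )
  for (cfg in configs) {
    b <- build_matched_baseline(default_schema(), cfg)
    expect_lte(b$parity$relative_diff, 0.10)
    expect_equal(b$parity$baseline, count_parameters(b))
  }
  # minimal one-feature-per-group schema still satisfies parity
  b1 <- build_matched_baseline(tiny_schema(per_group = 1L), ad_model_config(seed = 2))
  expect_lte(b1$parity$relative_diff, 0.10)
})

test_that("forward maps normalized rows to three severities in [0, 1]", {
  m <- build_model(schema, ad_model_config(seed = 5))
  co <- tiny_cohort(schema, n = 10, seed = 6)
  pred <- forward(m, co)
  expect_named(pred, c("patient_id", "lv", "pca", "fv"))
  for (s in c("lv", "pca", "fv")) {
    expect_true(all(pred[[s]] >= 0 & pred[[s]] <= 1))
  }
  # identical rows produce identical outputs
  co2 <- co[c(1, 1, 1), ]
  p2 <- forward(m, co2)
  expect_equal(p2[1, -1], p2[2, -1])
  # batch prediction equals row-by-row prediction
  rowwise <- purrr::map_dfr(seq_len(nrow(co)), ~ forward(m, co[.x, ]))
  expect_equal(pred, rowwise)
  # non-normalized input is rejected
  bad <- co
  bad$G1_f1[1] <- 1.2
  expect_error(forward(m, bad), "normalized")
})

test_that("permuting features within a group leaves predictions unchanged", {
  m <- build_model(schema, ad_model_config(seed = 8))
  co <- tiny_cohort(schema, n = 6, seed = 9)
  # swap the two G2 features in both the schema ordering and the embeddings
  m_perm <- m
  m_perm$groups$G2_biochem <- rev(m$groups$G2_biochem)
  m_perm$params$embed_W$G2_biochem <- m$params$embed_W$G2_biochem[2:1, ]
  m_perm$params$embed_B$G2_biochem <- m$params$embed_B$G2_biochem[2:1, ]
  expect_equal(forward(m_perm, co), forward(m, co))
})

test_that("analytic gradients match finite differences", {
  sch <- tiny_schema()
  co <- tiny_cohort(sch, n = 5, seed = 11)
  Y <- as.matrix(random_labels(co$patient_id, seed = 12)[, c("lv", "pca", "fv")])
  for (kind in c("modular", "mlp")) {
    model <- if (kind == "modular") {
      build_model(sch, ad_model_config(d = 3, hidden = c(6), activation = "tanh", seed = 13))
    } else {
      build_matched_baseline(sch, ad_model_config(d = 3, hidden = c(6), activation = "tanh", seed = 13))
    }
    mats <- adattn:::model_matrices(model, co)
    for (loss in c("bce", "mse")) {
      g <- adattn:::model_grad_matrix(model, mats, Y, loss)
      expect_equal(adattn:::eval_loss(model, mats, Y, loss), g$loss,
                   tolerance = 1e-10)
      got <- adattn:::flatten_params(g$grads)
      num <- numeric_gradient(model, mats, Y, loss)
      expect_equal(got, num, tolerance = 1e-6)
    }
  }
})

test_that("softmax output mode returns a probability simplex", {
  m <- build_model(schema, ad_model_config(output = "softmax", seed = 3))
  co <- tiny_cohort(schema, n = 4, seed = 4)
  pred <- forward(m, co)
  expect_equal(pred$lv + pred$pca + pred$fv, rep(1, 4), tolerance = 1e-9)
})

test_that("models round-trip through JSON serialization", {
  m <- build_model(schema, ad_model_config(seed = 17))
  co <- tiny_cohort(schema, n = 5, seed = 18)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(forward(back, co), forward(m, co), tolerance = 1e-12)
  expect_identical(back$kind, "modular")
  b <- build_matched_baseline(schema, ad_model_config(seed = 17))
  write_model(b, path)
  expect_equal(forward(read_model(path), co), forward(b, co), tolerance = 1e-12)
})

test_that("attention weights export in tidy row-stochastic form", {
  m <- build_model(schema, ad_model_config(seed = 19))
  co <- tiny_cohort(schema, n = 3, seed = 20)
  aw <- attention_weights(m, co, "G1_blood")
  expect_equal(nrow(aw), 3 * 2 * 2)
  sums <- dplyr::summarise(aw, s = sum(weight), .by = c("patient_id", "from"))
  expect_equal(sums$s, rep(1, 6), tolerance = 1e-9)
})
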