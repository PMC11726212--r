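schema <- tiny_schema()

test_that("mean imputation uses observed training means and fills all gaps", {
  co <- tiny_cohort(schema, n = 3, seed = 1)
  co$G1_f1 <- c(2, NA, 4)
  imp <- fit_imputer(co, schema)
  expect_equal(imp$mean[imp$feature == "G1_f1"], 3)
  filled <- apply_imputer(co, imp)
  expect_equal(filled$G1_f1, c(2, 3, 4))
  expect_false(anyNA(filled[, -1]))
  # observed entries untouched; complete tables pass through unchanged
  complete <- tiny_cohort(schema, n = 4, seed = 2)
  imp2 <- fit_imputer(complete, schema)
  expect_equal(imp2$mean, unname(colMeans(complete[, schema$name])))
  expect_identical(apply_imputer(complete, imp2), complete)
  # two gaps in one column receive the same mean
  co2 <- tiny_cohort(schema, n = 4, seed = 3)
  co2$MMSE[c(1, 3)] <- NA
  f2 <- apply_imputer(co2, fit_imputer(co2, schema))
  expect_equal(f2$MMSE[1], f2$MMSE[3])
  # imputation preserves the training mean exactly
  expect_equal(mean(f2$MMSE), mean(co2$MMSE, na.rm = TRUE))
})

test_that("an all-missing feature cannot be imputed", {
  co <- tiny_cohort(schema, n = 3, seed = 4)
  co$B2MG <- NA_real_
  expect_error(fit_imputer(co, schema), "B2MG")
})

test_that("reference-range min-max normalization maps the clinical range onto [0, 1]", {
  co <- tiny_cohort(schema, n = 4, seed = 5)
  co$B2MG <- c(1, 3, 2, 4)  # mg/L against the 1-3 reference range
  nz <- fit_normalizer(co, schema)
  expect_equal(unlist(nz[nz$feature == "B2MG", c("low", "high")]),
               c(low = 1, high = 3))
  normed <- normalize_cohort(co, nz)
  expect_equal(normed$B2MG, c(0, 1, 0.5, 1))  # 4 mg/L clips to 1
  expect_true(all(as.matrix(normed[, -1]) >= 0 & as.matrix(normed[, -1]) <= 1))
})

test_that("normalization is monotone and idempotent on in-range data", {
  co <- tiny_cohort(schema, n = 20, seed = 6)
  nz <- fit_normalizer(co, schema)
  normed <- normalize_cohort(co, nz)
  for (f in c("B2MG", "MMSE", "G3_f1")) {
    ord <- order(co[[f]])
    expect_true(all(diff(normed[[f]][ord]) >= 0))
  }
  # features with unit reference ranges are already normalized: identity
  renz <- fit_normalizer(normed, schema)
  again <- normalize_cohort(normed, renz)
  expect_equal(again$G1_f1, normed$G1_f1)
  # degenerate bounds are rejected
  const <- co
  sch_norange <- schema
  sch_norange$ref_low[1] <- NA; sch_norange$ref_high[1] <- NA
  const[[schema$name[1]]] <- 1
  expect_error(fit_normalizer(const, sch_norange), "Degenerate")
})

test_that("splits use largest-remainder sizes with ties to the earlier split", {
  expect_equal(adattn:::largest_remainder(430, c(0.70, 0.15, 0.15)),
               c(301L, 65L, 64L))
  expect_equal(adattn:::largest_remainder(10, c(0.7, 0.15, 0.15)),
               c(7L, 2L, 1L))
  expect_equal(adattn:::largest_remainder(100, c(0.70, 0.15, 0.15)),
               c(70L, 15L, 15L))
})

test_that("split_cohort partitions patients deterministically under a seed", {
  co <- tiny_cohort(schema, n = 20, seed = 7)
  lab <- random_labels(co$patient_id, seed = 7)
  s1 <- split_cohort(co, lab, seed = 11)
  s2 <- split_cohort(co, lab, seed = 11)
  expect_identical(s1, s2)
  ids <- unlist(purrr::map(s1, ~ .x$cohort$patient_id))
  expect_setequal(ids, co$patient_id)
  expect_equal(length(ids), 20L)  # disjoint and exhaustive
  expect_equal(vapply(s1, function(x) nrow(x$cohort), integer(1)),
               c(train = 14L, val = 3L, test = 3L))
  # labels stay aligned with their patients
  for (part in s1) {
    expect_identical(part$cohort$patient_id, part$labels$patient_id)
  }
  expect_error(split_cohort(co[1:2, ], lab[1:2, ]), "at least 3")
})

test_that("SMOTE interpolates on parent segments and equalizes strata", {
  x <- rbind(matrix(rnorm(20), 10, 2), c(0, 0), c(1, 1))
  strata <- c(rep("maj", 10), "min", "min")
  res <- smote(x, strata, k = 1, seed = 42)
  expect_equal(as.integer(table(res$strata)), c(10L, 10L))
  syn <- res$x[-(1:12), , drop = FALSE]
  # with two diagonal minority points every synthetic point is (u, u)
  expect_equal(syn[, 1], syn[, 2])
  expect_true(all(syn >= 0 & syn <= 1))
  # original rows preserved verbatim
  expect_identical(res$x[1:12, ], x)
})

test_that("SMOTE is a no-op on balanced strata and rejects degenerate input", {
  x <- matrix(rnorm(12), 6, 2)
  strata <- rep(c("a", "b"), each = 3)
  res <- smote(x, strata, seed = 1)
  expect_identical(res$x, x)
  expect_identical(res$strata, strata)
  expect_equal(nrow(res$synthetic), 0L)
  expect_error(smote(x, c("a", rep("b", 5)), seed = 1), "size 1")
  expect_error(smote(x, strata, k = 0), "at least 1")
})

test_that("synthetic rows stay inside their stratum's coordinate bounds", {
  withr::with_seed(9, {
    x <- matrix(runif(60), 20, 3)
    strata <- c(rep("maj", 15), rep("min", 5))
  })
  res <- smote(x, strata, k = 3, seed = 10)
  syn <- res$x[-(1:20), , drop = FALSE]
  mins <- apply(x[16:20, ], 2, min)
  maxs <- apply(x[16:20, ], 2, max)
  for (j in 1:3) {
    expect_true(all(syn[, j] >= mins[j] - 1e-12 & syn[, j] <= maxs[j] + 1e-12))
  }
})

test_that("the pipeline keeps SMOTE away from validation and test splits", {
  gen <- generate_cohort(cohort_config(n = 60, seed = 21))
  labels <- gen$truth[, c("patient_id", "lv", "pca", "fv")]
  pp <- suppressWarnings(
    preprocess_cohort(gen$cohort, labels, default_schema(), seed = 21))
  expect_equal(nrow(pp$val$cohort), 9L)
  expect_equal(nrow(pp$test$cohort), 9L)
  expect_gte(nrow(pp$train$cohort), 42L)  # only train may grow
  for (part in pp[c("train", "val", "test")]) {
    m <- as.matrix(part$cohort[, -1])
    expect_false(anyNA(m))
    expect_true(all(m >= 0 & m <= 1))
    expect_true(all(part$labels$lv >= 0 & part$labels$lv <= 1))
    expect_identical(part$cohort$patient_id, part$labels$patient_id)
  }
})
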