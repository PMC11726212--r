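test_that("overall severity is the mean of the three subtype severities", {
  expect_equal(overall_severity(data.frame(lv = 0, pca = 0, fv = 0)), 0)
  expect_equal(overall_severity(data.frame(lv = 1, pca = 1, fv = 1)), 1)
  expect_equal(overall_severity(data.frame(lv = 0.2, pca = 0.4, fv = 0.9)), 0.5)
  # permutation-invariant and monotone in each argument
  withr::with_seed(1, {
    s <- runif(3)
    perms <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
    vals <- vapply(perms, function(p) {
      overall_severity(setNames(as.data.frame(as.list(s[p])), c("lv", "pca", "fv")))
    }, numeric(1))
    expect_true(all(abs(vals - vals[1]) < 1e-12))
  })
  lo <- overall_severity(data.frame(lv = 0.2, pca = 0.3, fv = 0.4))
  hi <- overall_severity(data.frame(lv = 0.2, pca = 0.35, fv = 0.4))
  expect_gt(hi, lo)
})

test_that("subtype calls threshold severities with an inclusive boundary", {
  y <- data.frame(lv = 0.6, pca = 0.4, fv = 0.5)
  expect_equal(unlist(call_subtypes(y)), c(lv = TRUE, pca = FALSE, fv = TRUE))
  expect_equal(unlist(call_subtypes(data.frame(lv = 0, pca = 0, fv = 0))),
               c(lv = FALSE, pca = FALSE, fv = FALSE))
  expect_equal(unlist(call_subtypes(y, tau = 0.9)),
               c(lv = FALSE, pca = FALSE, fv = FALSE))
  expect_error(call_subtypes(y, tau = 1), "inside \\(0, 1\\)")
})

test_that("severity bins use upper-edge intervals and are monotone", {
  expect_equal(as.character(bin_severity(c(0.25, 0.26, 1.0, 0, 0.5, 0.75))),
               c("asymptomatic", "mild", "severe", "asymptomatic", "mild",
                 "moderate"))
  withr::with_seed(2, s <- sort(runif(100)))
  lv <- bin_severity(s)
  expect_true(all(diff(as.integer(lv)) >= 0))
  expect_false(anyNA(lv))  # bins partition [0, 1]
  expect_error(bin_severity(1.2), "\\[0, 1\\]")
})

test_that("f1 is the harmonic mean and sits below the other means", {
  expect_equal(f1(0.5, 0.5), 0.5)
  expect_warning(z <- f1(0, 0), "undefined")
  expect_equal(z, 0)
  withr::with_seed(3, {
    p <- runif(50, 0.05, 1)
    r <- runif(50, 0.05, 1)
  })
  v <- f1(p, r)
  expect_true(all(v <= sqrt(p * r) + 1e-12))
  expect_true(all(sqrt(p * r) <= (p + r) / 2 + 1e-12))
})

test_that("subtype metrics implement the standard 2x2 definitions", {
  ids <- sprintf("P%02d", 1:4)
  perfect <- tibble::tibble(patient_id = ids, lv = c(0.9, 0.1, 0.8, 0.2),
                            pca = c(0.7, 0.6, 0.1, 0.3),
                            fv = c(0.1, 0.9, 0.2, 0.6))
  mp <- subtype_metrics(perfect, perfect)
  expect_true(all(mp$accuracy == 1 & mp$precision == 1 & mp$recall == 1 &
                  mp$f1 == 1))
  expect_true(all(mp$fp == 0 & mp$fn == 0))

  # all-absent predictions on balanced truth: accuracy 0.5, recall 0
  none <- tibble::tibble(patient_id = ids, lv = 0, pca = 0, fv = 0)
  truth <- tibble::tibble(patient_id = ids, lv = c(1, 1, 0, 0),
                          pca = c(1, 0, 1, 0), fv = c(0, 1, 0, 1))
  mn <- subtype_metrics(none, truth)
  expect_equal(mn$accuracy, rep(0.5, 3))
  expect_equal(mn$recall, rep(0, 3))

  # hand-counted micro-example: TP = FP = FN = TN = 1 for lv
  pred <- tibble::tibble(patient_id = ids, lv = c(0.9, 0.8, 0.1, 0.2),
                         pca = 0, fv = 0)
  tru <- tibble::tibble(patient_id = ids, lv = c(1, 0, 1, 0), pca = 0, fv = 0)
  m1 <- subtype_metrics(pred, tru)[1, ]
  expect_equal(unlist(m1[, c("tp", "fp", "fn", "tn")]),
               c(tp = 1, fp = 1, fn = 1, tn = 1))
  expect_equal(unlist(m1[, c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 0.5, precision = 0.5, recall = 0.5, f1 = 0.5))
})

test_that("overall subtype accuracy is the unweighted mean", {
  expect_equal(overall_subtype_accuracy(c(1, 1, 1)), 1)
  expect_equal(overall_subtype_accuracy(c(0, 0.5, 1)), 0.5)
})

test_that("severity accuracy is class-conditional with absent levels excluded", {
  tru <- bin_severity(c(0.1, 0.1, 0.4, 0.4, 0.6, 0.9))
  prd <- bin_severity(c(0.1, 0.4, 0.4, 0.4, 0.6, 0.6))
  sa <- severity_accuracy(prd, tru)
  expect_equal(sa$per_level$accuracy, c(0.5, 1, 1, 0))
  expect_equal(sa$overall, mean(c(0.5, 1, 1, 0)))

  tru2 <- bin_severity(c(0.1, 0.4))  # moderate and severe absent
  prd2 <- bin_severity(c(0.1, 0.4))
  expect_warning(sa2 <- severity_accuracy(prd2, tru2), "absent")
  expect_equal(sa2$overall, 1)
  expect_equal(sum(is.na(sa2$per_level$accuracy)), 2L)
})

test_that("reports are internally consistent and round-trip through files", {
  withr::with_seed(4, {
    ids <- sprintf("P%03d", 1:80)
    truth <- random_labels(ids, seed = 5)
    pred <- truth
    pred$lv <- pmin(1, pmax(0, pred$lv + rnorm(80, 0, 0.2)))
    pred$pca <- pmin(1, pmax(0, pred$pca + rnorm(80, 0, 0.2)))
    pred$fv <- pmin(1, pmax(0, pred$fv + rnorm(80, 0, 0.2)))
  })
  rep <- evaluate_predictions(pred, truth)
  expect_equal(rep$overall$subtype_accuracy, mean(rep$subtype$accuracy))
  expect_equal(rep$overall$severity_accuracy,
               mean(rep$severity$accuracy, na.rm = TRUE))
  expect_true(all(rep$subtype$tp + rep$subtype$fp + rep$subtype$fn +
                  rep$subtype$tn == 80))

  dir <- withr::local_tempdir()
  write_report(rep, dir)
  back <- read_report(dir)
  expect_equal(back$subtype$accuracy, rep$subtype$accuracy)
  expect_equal(back$severity$accuracy, rep$severity$accuracy)
  expect_equal(back$overall, rep$overall)
  expect_equal(back$n, rep$n)

  # perfect predictions give an all-ones report
  perf <- evaluate_predictions(truth, truth)
  expect_true(all(perf$subtype$accuracy == 1))
  expect_equal(perf$overall$subtype_accuracy, 1)

  td <- tidy(rep)
  expect_named(td, c("section", "class", "metric", "value"))
  expect_s3_class(autoplot(rep), "ggplot")
})
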