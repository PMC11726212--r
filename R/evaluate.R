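#' Label design and evaluation
#'
#' The model's target is a triple of subtype severities in \[0, 1\]
#' (logopenic variant `lv`, posterior cortical atrophy `pca`, frontal
#' variant `fv`).  A subtype is called present when its severity is at
#' least the threshold `tau` (0.5 by default, boundary inclusive).  Overall
#' disease severity is the arithmetic mean of the three severities, binned
#' into four ordered levels at thresholds 0.25 / 0.5 / 0.75 / 1.0, each
#' threshold being the *top* of its level: \[0, 0.25\] asymptomatic,
#' (0.25, 0.5\] mild, (0.5, 0.75\] moderate, (0.75, 1\] severe.
#'
#' @name ad_labels
NULL

#' Severity level names, in order
#' @return Character vector of the four ordered levels.
#' @export
severity_levels <- function() c("asymptomatic", "mild", "moderate", "severe")

#' Overall disease severity
#'
#' The arithmetic mean of the three subtype severities.
#'
#' @param labels Label tibble (or data frame) with columns `lv, pca, fv` in
#'   \[0, 1\].
#' @return Numeric vector of overall severities.
#' @examples
#' overall_severity(data.frame(lv = 0.2, pca = 0.4, fv = 0.9))
#' @export
overall_severity <- function(labels) {
  for (s in c("lv", "pca", "fv")) check_prob(labels[[s]], s)
  rowMeans(cbind(labels$lv, labels$pca, labels$fv))
}

#' Call subtype presence by thresholding severities
#'
#' @param labels Label tibble with `lv, pca, fv` severities.
#' @param tau Presence threshold in (0, 1); a severity equal to `tau`
#'   counts as present.
#' @return Tibble of logical columns `lv, pca, fv` (plus `patient_id` if
#'   present in the input).
#' @export
call_subtypes <- function(labels, tau = 0.5) {
  if (!is_number(tau) || tau <= 0 || tau >= 1) {
    abort("`tau` must be a single number strictly inside (0, 1).")
  }
  for (s in c("lv", "pca", "fv")) check_prob(labels[[s]], s)
  out <- tibble::tibble(lv = labels$lv >= tau, pca = labels$pca >= tau,
                        fv = labels$fv >= tau)
  if ("patient_id" %in% names(labels)) {
    out <- dplyr::bind_cols(tibble::tibble(patient_id = labels$patient_id), out)
  }
  out
}

#' Bin a continuous severity into ordinal levels
#'
#' Upper-edge half-open bins: \[0, 0.25\] asymptomatic, (0.25, 0.5\] mild,
#' (0.5, 0.75\] moderate, (0.75, 1\] severe.
#'
#' @param s Numeric vector of severities in \[0, 1\].
#' @return Ordered factor over [severity_levels()].
#' @examples
#' bin_severity(c(0.25, 0.26, 1.0))
#' @export
bin_severity <- function(s) {
  check_prob(s, "s")
  cut(s, breaks = c(-Inf, 0.25, 0.5, 0.75, Inf),
      labels = severity_levels(), right = TRUE, ordered_result = TRUE)
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 p r / (p + r)`; defined as 0 (with a warning) when both
#' are zero.
#'
#' @param precision,recall Rates in \[0, 1\] (vectorized).
#' @return Numeric vector of F1 scores.
#' @examples
#' f1(0.90, 0.91)  # 0.905
#' @export
f1 <- function(precision, recall) {
  check_prob(precision, "precision")
  check_prob(recall, "recall")
  out <- numeric(length(precision))
  zero <- precision + recall == 0
  if (any(zero)) warn("F1 undefined where precision = recall = 0; returning 0.")
  out[!zero] <- 2 * precision[!zero] * recall[!zero] /
    (precision[!zero] + recall[!zero])
  out
}

align_labels <- function(pred, truth) {
  if ("patient_id" %in% names(pred) && "patient_id" %in% names(truth)) {
    if (!setequal(pred$patient_id, truth$patient_id)) {
      abort("Predicted and true label tables have mismatched patient ids.")
    }
    truth <- truth[match(pred$patient_id, truth$patient_id), ]
  } else if (nrow(pred) != nrow(truth)) {
    abort("Predicted and true label tables have different sizes and no ids to join on.")
  }
  list(pred = pred, truth = truth)
}

#' Per-subtype classification metrics
#'
#' Thresholds predicted and true severities at `tau` and computes, per
#' subtype, the 2x2 confusion counts and accuracy `(TP+TN)/n`, precision,
#' recall and F1.
#'
#' @param pred,truth Label tibbles of severities (aligned by `patient_id`
#'   when present).
#' @param tau Presence threshold (default 0.5).
#' @return Tibble with one row per subtype: `subtype, tp, fp, fn, tn,
#'   accuracy, precision, recall, f1`.
#' @export
subtype_metrics <- function(pred, truth, tau = 0.5) {
  al <- align_labels(pred, truth)
  if (nrow(al$pred) == 0L) abort("Cannot evaluate an empty label table.")
  pc <- call_subtypes(al$pred, tau)
  tc <- call_subtypes(al$truth, tau)
  purrr::map_dfr(c("lv", "pca", "fv"), function(s) {
    p <- pc[[s]]; y <- tc[[s]]
    tp <- sum(p & y); fp <- sum(p & !y); fn <- sum(!p & y); tn <- sum(!p & !y)
    n <- tp + fp + fn + tn
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    tibble::tibble(
      subtype = s, tp = tp, fp = fp, fn = fn, tn = tn,
      accuracy = (tp + tn) / n,
      precision = prec, recall = rec,
      f1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    )
  })
}

#' Overall subtype accuracy
#'
#' Unweighted mean of the per-subtype accuracies.
#'
#' @param accuracies Numeric vector of per-subtype accuracy rates.
#' @return Single rate.
#' @examples
#' overall_subtype_accuracy(c(0.814, 0.836, 0.842))  # 0.8307
#' @export
overall_subtype_accuracy <- function(accuracies) {
  check_prob(accuracies, "accuracies")
  mean(accuracies)
}

#' Per-level and overall severity accuracy
#'
#' Per-level accuracy is class-conditional: among patients whose *true*
#' level is L, the fraction predicted as L.  The overall severity accuracy
#' is the unweighted mean of the defined per-level accuracies; levels absent
#' from the truth are reported as `NA` and excluded with a warning.
#'
#' @param pred_levels,true_levels Vectors coercible to the ordered severity
#'   levels (factors from [bin_severity()] or their character values).
#' @return List with `per_level` (tibble `level, n, accuracy`) and
#'   `overall` (rate).
#' @export
severity_accuracy <- function(pred_levels, true_levels) {
  lv <- severity_levels()
  pred_levels <- factor(as.character(pred_levels), levels = lv)
  true_levels <- factor(as.character(true_levels), levels = lv)
  if (length(pred_levels) != length(true_levels)) {
    abort("Predicted and true level vectors must have equal length.")
  }
  per <- purrr::map_dfr(lv, function(L) {
    in_class <- true_levels == L
    tibble::tibble(
      level = L, n = sum(in_class),
      accuracy = if (sum(in_class) == 0) NA_real_
                 else mean(pred_levels[in_class] == L)
    )
  })
  if (anyNA(per$accuracy)) {
    warn(paste0("True level(s) absent, excluded from overall severity accuracy: ",
                paste(per$level[is.na(per$accuracy)], collapse = ", ")))
  }
  list(per_level = per, overall = mean(per$accuracy, na.rm = TRUE))
}

#' Build a full evaluation report
#'
#' Aggregates per-subtype metrics (with confusion counts), per-level and
#' overall severity accuracy, and the overall subtype accuracy into one
#' object.  Severity levels are derived by binning the mean of the three
#' severities for both prediction and truth.
#'
#' @param pred Predicted label tibble (severities).
#' @param truth True label tibble.
#' @param tau Presence threshold (default 0.5).
#' @return An `ad_report`: list with tibbles `subtype`, `severity`,
#'   `overall`, plus `tau` and `n`.
#' @export
evaluate_predictions <- function(pred, truth, tau = 0.5) {
  al <- align_labels(pred, truth)
  sub <- subtype_metrics(al$pred, al$truth, tau)
  sev <- severity_accuracy(bin_severity(overall_severity(al$pred)),
                           bin_severity(overall_severity(al$truth)))
  out <- list(
    subtype = sub,
    severity = sev$per_level,
    overall = tibble::tibble(
      subtype_accuracy = overall_subtype_accuracy(sub$accuracy),
      severity_accuracy = sev$overall
    ),
    tau = tau,
    n = nrow(al$pred)
  )
  class(out) <- "ad_report"
  out
}

#' @export
print.ad_report <- function(x, ...) {
  cat(sprintf("<ad_report> n = %d patients, tau = %g\n", x$n, x$tau))
  cat(sprintf("  overall subtype accuracy:  %.1f%%\n",
              as_percent(x$overall$subtype_accuracy)))
  cat(sprintf("  overall severity accuracy: %.1f%%\n",
              as_percent(x$overall$severity_accuracy)))
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x An `ad_report`.
#' @param ... Unused.
#' @return Long tibble `section, class, metric, value`.
#' @export
tidy.ad_report <- function(x, ...) {
  dplyr::bind_rows(
    x$subtype |>
      tidyr::pivot_longer(c("accuracy", "precision", "recall", "f1"),
                          names_to = "metric", values_to = "value") |>
      dplyr::transmute(section = "subtype", class = .data$subtype,
                       metric = .data$metric, value = .data$value),
    x$severity |>
      dplyr::transmute(section = "severity", class = .data$level,
                       metric = "accuracy", value = .data$accuracy),
    tibble::tibble(section = "overall",
                   class = c("subtype", "severity"),
                   metric = "accuracy",
                   value = c(x$overall$subtype_accuracy,
                             x$overall$severity_accuracy))
  )
}

#' @export
glance.ad_report <- function(x, ...) {
  tibble::tibble(
    n = x$n, tau = x$tau,
    subtype_accuracy = x$overall$subtype_accuracy,
    severity_accuracy = x$overall$severity_accuracy
  )
}

#' Plot an evaluation report
#'
#' @param object An `ad_report`.
#' @param ... Unused.
#' @return A ggplot of per-class metric bars.
#' @export
autoplot.ad_report <- function(object, ...) {
  td <- tidy(object) |> dplyr::filter(.data$section != "overall")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$class, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~ .data$section, scales = "free_x") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "rate", title = "Evaluation report") +
    ggplot2::theme_minimal()
}

#' Write / read an evaluation report
#'
#' Emits `subtype.csv` (per-subtype metrics and confusion counts, the shape
#' of a per-subtype performance table), `severity.csv` (per-level
#' accuracies) and `report.json` (overall accuracies, `tau`, `n`) into a
#' directory; [read_report()] restores the `ad_report` exactly.
#'
#' @param report An `ad_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$subtype, file.path(dir, "subtype.csv"), progress = FALSE)
  readr::write_csv(report$severity, file.path(dir, "severity.csv"),
                   na = "", progress = FALSE)
  jsonlite::write_json(
    list(overall = as.list(report$overall), tau = report$tau, n = report$n),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_report
#' @export
read_report <- function(dir) {
  sub <- readr::read_csv(file.path(dir, "subtype.csv"),
                         col_types = "cnnnnnnnn", progress = FALSE)
  sev <- readr::read_csv(file.path(dir, "severity.csv"),
                         col_types = "cnn", na = "", progress = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "report.json"), simplifyVector = TRUE)
  out <- list(
    subtype = sub, severity = sev,
    overall = tibble::as_tibble(meta$overall),
    tau = meta$tau, n = meta$n
  )
  class(out) <- "ad_report"
  out
}
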