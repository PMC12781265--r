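#' Confusion matrix for binary ischemia classification
#'
#' Cells follow the a/b/c/d layout of diagnostic-test tables:
#' a = true positives, b = false positives, c = false negatives,
#' d = true negatives.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return An object of class `"confusion_matrix"`.
#' @export
confusion_matrix <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("confusion-matrix cells must be non-negative integers", call. = FALSE)
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
                 d = as.integer(d), total = as.integer(a + b + c + d)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion matrix: TP=%d FP=%d FN=%d TN=%d total=%d>\n",
              x$a, x$b, x$c, x$d, x$total))
  invisible(x)
}

#' Tally predictions against gold labels
#'
#' @param preds,golds Equal-length vectors of 0/1 values.
#' @return A [confusion_matrix()].
#' @examples
#' build_confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
build_confusion <- function(preds, golds) {
  if (length(preds) != length(golds))
    stop("preds (", length(preds), ") and golds (", length(golds),
         ") differ in length", call. = FALSE)
  if (length(preds) && (!all(preds %in% c(0, 1)) || !all(golds %in% c(0, 1))))
    stop("preds and golds must be binary (0/1)", call. = FALSE)
  confusion_matrix(a = sum(preds == 1 & golds == 1),
                   b = sum(preds == 1 & golds == 0),
                   c = sum(preds == 0 & golds == 1),
                   d = sum(preds == 0 & golds == 0))
}

# Half-up rounding: 92.45 -> 92.5 at one decimal. Base round() is
# round-half-even, which printed diagnostic tables do not use.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Compute the five evaluation metrics from a confusion matrix
#'
#' Sensitivity/recall = a/(a+c), specificity = d/(b+d), precision/PPV =
#' a/(a+b), NPV = d/(c+d), all as percentages; F1 =
#' 2 * precision * recall / (precision + recall), computed from the
#' *unrounded* precision and recall. All values are then rounded half-up to
#' `decimals` places. A zero denominator makes that metric `NA` (explicitly
#' not applicable — never silently 0).
#'
#' @param cm A [confusion_matrix()].
#' @param decimals Decimal places for rounding (default 1, as such tables
#'   are conventionally printed).
#' @return An object of class `"metrics_report"` with fields
#'   `sensitivity_recall`, `specificity`, `precision_ppv`, `npv`, `f1`
#'   (percent, or `NA`) and `total`.
#' @examples
#' compute_metrics(confusion_matrix(37, 5, 1, 56))
#' @export
compute_metrics <- function(cm, decimals = 1) {
  stopifnot(inherits(cm, "confusion_matrix"))
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  sens <- ratio(cm$a, cm$a + cm$c)
  spec <- ratio(cm$d, cm$b + cm$d)
  prec <- ratio(cm$a, cm$a + cm$b)
  npv <- ratio(cm$d, cm$c + cm$d)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  vals <- round_half_up(c(sensitivity_recall = sens, specificity = spec,
                          precision_ppv = prec, npv = npv, f1 = f1), decimals)
  structure(c(as.list(vals), list(total = cm$total, decimals = decimals)),
            class = "metrics_report")
}

METRIC_LABELS <- c(sensitivity_recall = "Sensitivity/Recall",
                   specificity = "Specificity",
                   precision_ppv = "Precision/PPV",
                   npv = "Negative Predictive Value",
                   f1 = "F1")

format_pct <- function(x) {
  if (is.na(x)) return("NA")
  if (x == round(x)) sprintf("%d%%", as.integer(round(x))) else
    paste0(format(x, nsmall = 1), "%")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics over %d documents>\n", x$total))
  for (k in names(METRIC_LABELS))
    cat(sprintf("  %-26s %s\n", METRIC_LABELS[[k]], format_pct(x[[k]])))
  invisible(x)
}

#' Evaluate classifications against gold labels
#'
#' Joins predictions to gold labels on `report_id` (order-independent), then
#' builds the confusion matrix and metrics. Every prediction's `report_id`
#' must appear exactly once among the golds.
#'
#' @param results List of `document_classification` objects (or a
#'   `corpus_classification`).
#' @param golds A data frame with columns `report_id` and `gold_label`, or a
#'   list of `report_document`s carrying gold labels.
#' @return A list with elements `metrics` (a `metrics_report`) and
#'   `confusion` (a [confusion_matrix()]).
#' @export
evaluate_predictions <- function(results, golds) {
  if (inherits(results, "corpus_classification")) results <- results$results
  if (!is.data.frame(golds)) {
    golds <- data.frame(
      report_id = vapply(golds, `[[`, character(1), "report_id"),
      gold_label = vapply(golds, `[[`, integer(1), "gold_label"),
      stringsAsFactors = FALSE)
  }
  dup <- unique(golds$report_id[duplicated(golds$report_id)])
  if (length(dup))
    stop("duplicate gold report_id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  ids <- vapply(results, `[[`, character(1), "report_id")
  missing <- setdiff(ids, golds$report_id)
  if (length(missing))
    stop("no gold label for report_id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  preds <- vapply(results, `[[`, integer(1), "ischemia")
  gl <- golds$gold_label[match(ids, golds$report_id)]
  if (anyNA(gl))
    stop("gold labels contain NA for joined report_ids", call. = FALSE)
  cm <- build_confusion(preds, gl)
  list(metrics = compute_metrics(cm), confusion = cm)
}

#' Write an evaluation report as CSV or aligned text
#'
#' `metrics_as_row()` flattens one evaluation into a single data frame row
#' (cells a–d, total, and the five metrics); `write_metrics_csv()` writes one
#' or more such rows; `format_metrics_table()` renders an aligned plain-text
#' table in conventional row order.
#'
#' @param eval_result A list with `metrics` and `confusion`, as returned by
#'   [evaluate_predictions()].
#' @param model Label for the row.
#' @return `metrics_as_row()`: a one-row data frame.
#' @export
metrics_as_row <- function(eval_result, model = "model") {
  cm <- eval_result$confusion
  m <- eval_result$metrics
  data.frame(model = model, true_positives = cm$a, false_positives = cm$b,
             false_negatives = cm$c, true_negatives = cm$d, total = cm$total,
             sensitivity_recall = m$sensitivity_recall,
             specificity = m$specificity, precision_ppv = m$precision_ppv,
             npv = m$npv, f1 = m$f1, stringsAsFactors = FALSE)
}

#' @rdname metrics_as_row
#' @param rows A data frame of rows from [metrics_as_row()].
#' @param path Output file path.
#' @export
write_metrics_csv <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname metrics_as_row
#' @export
format_metrics_table <- function(eval_result, model = "model") {
  cm <- eval_result$confusion
  m <- eval_result$metrics
  lines <- c(
    sprintf("%-28s %s", "Parameter", model),
    sprintf("%-28s %d", "True Positives (a)", cm$a),
    sprintf("%-28s %d", "False Positives (b)", cm$b),
    sprintf("%-28s %d", "False Negatives (c)", cm$c),
    sprintf("%-28s %d", "True Negatives (d)", cm$d),
    sprintf("%-28s %d", "Total (a+b+c+d)", cm$total),
    vapply(names(METRIC_LABELS), function(k)
      sprintf("%-28s %s", METRIC_LABELS[[k]], format_pct(m[[k]])),
      character(1)))
  paste(lines, collapse = "\n")
}
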