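#' Evaluation against a curator gold standard
#'
#' Annotation quality is validated against a set of assays independently
#' labelled by database curators. The comparison scores the *binary* decision
#' — did the pipeline annotate the assay at all, and did a curator assign any
#' experiment or phenotype phrase — in a 2x2 confusion matrix. Gold rows
#' flagged `excluded` (assays that turned out not to be in vivo at all) are
#' removed before counting, so a 500-assay gold set with 12 exclusions scores
#' 488 assays.
#'
#' @name evaluation
NULL

#' Confusion matrix of predicted vs curator annotation
#'
#' @param predictions Tibble with columns `assay_id` and `annotated`
#'   (logical), typically the `summary` of [annotate_corpus()].
#' @param gold Tibble with columns `assay_id`, `curator_positive` (logical or
#'   0/1) and optionally `excluded` (logical or 0/1, default `FALSE`).
#'   Duplicate gold `assay_id`s are an error.
#' @param strict_missing If `TRUE`, a gold assay with no prediction row is an
#'   error; by default it counts as predicted-negative with a warning.
#' @return A list of class `invivo_confusion` with integer fields `tp`, `fn`,
#'   `fp`, `tn` and `n_scored`, `n_excluded`.
#' @examples
#' gold <- tibble::tibble(assay_id = c("a", "b", "c", "d"),
#'                        curator_positive = c(TRUE, FALSE, FALSE, TRUE))
#' pred <- tibble::tibble(assay_id = c("a", "b", "c", "d"),
#'                        annotated = c(TRUE, FALSE, TRUE, FALSE))
#' confusion_matrix(pred, gold)
#' @export
confusion_matrix <- function(predictions, gold, strict_missing = FALSE) {
  predictions <- tibble::as_tibble(predictions)
  gold <- tibble::as_tibble(gold)
  dup <- unique(gold$assay_id[duplicated(gold$assay_id)])
  if (length(dup) > 0L) {
    stop("duplicate assay_id in gold standard: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (!"excluded" %in% names(gold)) gold$excluded <- FALSE
  gold$excluded <- as.logical(gold$excluded)
  gold$curator_positive <- as.logical(gold$curator_positive)
  n_excluded <- sum(gold$excluded)
  scored <- gold[!gold$excluded, , drop = FALSE]
  idx <- match(scored$assay_id, predictions$assay_id)
  if (anyNA(idx)) {
    missing_ids <- scored$assay_id[is.na(idx)]
    if (strict_missing) {
      stop("no prediction for gold assay_id: ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    }
    warning(sprintf("%d gold assay(s) without a prediction counted as predicted-negative",
                    length(missing_ids)), call. = FALSE)
  }
  pred_pos <- ifelse(is.na(idx), FALSE, predictions$annotated[idx])
  actual_pos <- scored$curator_positive
  structure(
    list(
      tp = sum(pred_pos & actual_pos),
      fn = sum(!pred_pos & actual_pos),
      fp = sum(pred_pos & !actual_pos),
      tn = sum(!pred_pos & !actual_pos),
      n_scored = nrow(scored),
      n_excluded = n_excluded
    ),
    class = "invivo_confusion"
  )
}

#' Build a confusion-matrix object from its four cells
#'
#' @param tp,fn,fp,tn Non-negative counts.
#' @return An `invivo_confusion` object.
#' @export
confusion_cells <- function(tp, fn, fp, tn) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  structure(
    list(tp = tp, fn = fn, fp = fp, tn = tn,
         n_scored = tp + fn + fp + tn, n_excluded = 0L),
    class = "invivo_confusion"
  )
}

#' @export
print.invivo_confusion <- function(x, ...) {
  cat(sprintf("Confusion matrix (n=%d scored", x$n_scored))
  if (x$n_excluded > 0) cat(sprintf(", %d excluded", x$n_excluded))
  cat(")\n")
  cat(sprintf("  TP=%d  FN=%d\n  FP=%d  TN=%d\n", x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Classification statistics from a confusion matrix
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)` and F1 `2TP/(2TP+FP+FN)`. A statistic whose denominator is
#' zero is reported as `NA` (undefined), never as 0. Values are returned at
#' full precision; round to two decimals for display.
#'
#' @param cm An `invivo_confusion` object (or list with `tp`, `fn`, `fp`,
#'   `tn`).
#' @return A list of class `invivo_class_stats` with `sensitivity`,
#'   `specificity`, `precision`, `f1`.
#' @examples
#' classification_stats(confusion_cells(tp = 315, fn = 63, fp = 36, tn = 74))
#' @export
classification_stats <- function(cm) {
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  structure(
    list(
      sensitivity = ratio(cm$tp, cm$tp + cm$fn),
      specificity = ratio(cm$tn, cm$tn + cm$fp),
      precision = ratio(cm$tp, cm$tp + cm$fp),
      f1 = ratio(2 * cm$tp, 2 * cm$tp + cm$fp + cm$fn)
    ),
    class = "invivo_class_stats"
  )
}

#' @export
print.invivo_class_stats <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f", v)
  cat("Classification statistics\n")
  cat(sprintf("  sensitivity: %s\n  specificity: %s\n  precision:   %s\n  F1 score:    %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$precision),
              fmt(x$f1)))
  invisible(x)
}
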