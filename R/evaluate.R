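#' Confusion counts for the pulse-selection task
#'
#' @param truth Logical vector: TRUE for pulses with a calculable P2/P1
#'   ratio (the positive class).
#' @param predicted Logical vector: TRUE for pulses kept by the selector.
#' @return An object of class `confusion_counts` with fields `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- as.logical(truth); predicted <- as.logical(predicted)
  stopifnot(length(truth) == length(predicted), length(truth) > 0)
  structure(list(tp = sum(truth & predicted), fp = sum(!truth & predicted),
                 tn = sum(!truth & !predicted), fn = sum(truth & !predicted)),
            class = "confusion_counts")
}

#' @rdname confusion_counts
#' @param tp,fp,tn,fn Non-negative counts (alternative direct constructor).
#' @export
confusion_from_counts <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_counts")
}

#' True- and false-positive rates in percent
#'
#' `TPR = 100 tp / (tp + fn)`, `FPR = 100 fp / (fp + tn)`.
#'
#' @param counts A `confusion_counts`.
#' @return Named numeric vector `c(tpr_pct, fpr_pct)`, unrounded.
#' @export
rates <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$tp + counts$fn == 0 || counts$fp + counts$tn == 0)
    icpr_stop("icpr_single_class", "rates are undefined with an empty class")
  c(tpr_pct = 100 * counts$tp / (counts$tp + counts$fn),
    fpr_pct = 100 * counts$fp / (counts$fp + counts$tn))
}

#' False-positive and false-negative shares of the whole dataset, percent
#'
#' @param counts A `confusion_counts`.
#' @return Named numeric vector `c(fp_pct_of_total, fn_pct_of_total)`.
#' @export
dataset_fractions <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$tp + counts$fp + counts$tn + counts$fn
  c(fp_pct_of_total = 100 * counts$fp / total,
    fn_pct_of_total = 100 * counts$fn / total)
}

#' Mean absolute appearance-time error, percent of pulse duration
#'
#' Computed over pulses where both truth and prediction are calculable:
#' `mean(|delta index| / 180) * 100`, separately for P1 and P2.
#'
#' @param true_labels Data frame with `p1`, `p2` (0 = non-calculable
#'   sentinel).
#' @param predicted Data frame with `i1`, `i2`, `calculable`.
#' @return Named numeric vector `c(p1_mae_pct, p2_mae_pct)`.
#' @export
appearance_mae <- function(true_labels, predicted) {
  stopifnot(nrow(true_labels) == nrow(predicted))
  both <- true_labels$p1 > 0 & true_labels$p2 > 0 & predicted$calculable
  if (!any(both))
    icpr_stop("icpr_empty_series", "no pulses are calculable in both truth and prediction")
  c(p1_mae_pct = mean(abs(predicted$i1[both] - true_labels$p1[both])) / PULSE_LEN * 100,
    p2_mae_pct = mean(abs(predicted$i2[both] - true_labels$p2[both])) / PULSE_LEN * 100)
}

#' Ratio error and ratio>1 detection accuracy
#'
#' `ratio_mae` is the mean absolute difference between true and predicted
#' P2/P1 ratios; `gt1_accuracy` is the fraction of pulses where the
#' predicted and true ratios agree on the clinically interpreted class
#' "P2/P1 ratio > 1" (a ratio of exactly 1 counts as the negative class).
#'
#' @param true_ratios,predicted_ratios Aligned numeric vectors.
#' @return Named numeric vector `c(ratio_mae, gt1_accuracy)`.
#' @export
ratio_eval <- function(true_ratios, predicted_ratios) {
  stopifnot(length(true_ratios) == length(predicted_ratios),
            length(true_ratios) > 0)
  ok <- !is.na(true_ratios) & !is.na(predicted_ratios)
  c(ratio_mae = mean(abs(true_ratios[ok] - predicted_ratios[ok])),
    gt1_accuracy = mean((predicted_ratios[ok] > 1) == (true_ratios[ok] > 1)))
}

#' Metrics report for a selection + designation evaluation
#'
#' Assembles the figures of merit into a table mirroring the structure of
#' the pipeline's report: confusion counts, TPR/FPR, dataset fractions, and
#' - when designation results are supplied - appearance-time MAEs, ratio MAE
#' and ratio>1 accuracy. Designation metrics follow the convention of being
#' computed only on pulses with a labeled ratio that passed selection.
#'
#' @param counts A `confusion_counts` for the selection task.
#' @param true_labels,predicted Optional designation frames as in
#'   [appearance_mae()].
#' @param true_ratios,predicted_ratios Optional aligned ratio vectors.
#' @return A data frame `(metric, value)`; values unrounded, printed at one
#'   decimal (half-up) by the print method.
#' @export
evaluation_report <- function(counts, true_labels = NULL, predicted = NULL,
                              true_ratios = NULL, predicted_ratios = NULL) {
  r <- rates(counts)
  f <- dataset_fractions(counts)
  metric <- c("tp", "fp", "tn", "fn", "tpr_pct", "fpr_pct",
              "fp_pct_of_total", "fn_pct_of_total")
  value <- c(counts$tp, counts$fp, counts$tn, counts$fn, r, f)
  if (!is.null(true_labels) && !is.null(predicted)) {
    am <- appearance_mae(true_labels, predicted)
    metric <- c(metric, names(am)); value <- c(value, am)
  }
  if (!is.null(true_ratios)) {
    re <- ratio_eval(true_ratios, predicted_ratios)
    metric <- c(metric, "ratio_mae", "gt1_accuracy_pct")
    value <- c(value, re["ratio_mae"], 100 * re["gt1_accuracy"])
  }
  structure(data.frame(metric = metric, value = unname(value)),
            class = c("icpr_report", "data.frame"))
}

#' @export
print.icpr_report <- function(x, ...) {
  y <- x
  y$value <- round_half_up(y$value, 1)
  cat("ICP P2/P1 pipeline evaluation\n")
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
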