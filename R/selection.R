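#' Area under the ROC curve
#'
#' Trapezoidal area under the curve of true-positive rate against
#' false-positive rate over all score thresholds; equal to the probability
#' that a random positive outscores a random negative, with ties counting
#' one half.
#'
#' @param labels Logical (or 0/1) class labels.
#' @param scores Numeric scores, higher meaning more positive.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  y <- as.logical(labels)
  stopifnot(length(y) == length(scores))
  np <- sum(y); nn <- sum(!y)
  if (np == 0L || nn == 0L)
    icpr_stop("icpr_single_class", "AUC is undefined with a single class")
  # sweep thresholds downward through the distinct scores
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(yy); fp <- cumsum(!yy)
  last <- which(!duplicated(grp, fromLast = TRUE))  # end of each tie group
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Youden-optimal decision threshold
#'
#' Picks, from the finite candidate set of midpoints between consecutive
#' distinct scores (plus minus and plus infinity), the threshold maximizing
#' TPR - FPR, with a pulse classified positive when its score is greater
#' than or equal to the threshold. Ties resolve toward the higher threshold
#' (fewer positives).
#'
#' @inheritParams roc_auc
#' @return A list with `threshold`, `tpr`, `fpr` (rates as fractions).
#' @export
youden_threshold <- function(labels, scores) {
  y <- as.logical(labels)
  stopifnot(length(y) == length(scores))
  np <- sum(y); nn <- sum(!y)
  if (np == 0L || nn == 0L)
    icpr_stop("icpr_single_class", "Youden threshold is undefined with a single class")
  s <- sort(unique(scores))
  cand <- c(-Inf, if (length(s) > 1) (utils::head(s, -1) + utils::tail(s, -1)) / 2, Inf)
  best <- -Inf; best_thr <- Inf; best_tpr <- 0; best_fpr <- 0
  for (thr in cand) {
    pred <- scores >= thr
    tpr <- sum(pred & y) / np
    fpr <- sum(pred & !y) / nn
    j <- tpr - fpr
    if (j > best || (j == best && thr > best_thr)) {
      best <- j; best_thr <- thr; best_tpr <- tpr; best_fpr <- fpr
    }
  }
  list(threshold = best_thr, tpr = best_tpr, fpr = best_fpr)
}

#' Apply a trained selector at a decision threshold
#'
#' @param model A trained selection `icpr_model`.
#' @param pulses N x 180 matrix or `pulse_matrix`.
#' @param threshold Decision threshold on the sigmoid probability; pulses
#'   with probability >= threshold are kept.
#' @return Logical keep-mask of length N.
#' @export
select_pulses <- function(model, pulses, threshold = 0.5) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  predict_selection(model, pulses) >= threshold
}
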