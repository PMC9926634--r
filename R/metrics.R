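#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a uniformly chosen
#' positive outranks a uniformly chosen negative, with tied scores credited
#' 0.5. Computed from midranks, so it is exact for any tie pattern.
#'
#' @param scores numeric prediction scores (higher means more responder).
#' @param labels binary 0/1 vector.
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    stop("AUROC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: the sum over recall increments of the
#' precision at each threshold, without linear interpolation (trapezoids
#' overstate the area under class imbalance). Ties in scores are handled
#' by thresholding at distinct score values.
#'
#' @inheritParams auroc
#' @return average precision in `(0, 1]`; the chance level is the
#'   prevalence.
#' @examples
#' auprc(c(0.9, 0.8, 0.7), c(1, 0, 1))  # 0.8333
#' @export
auprc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  nPos <- sum(labels == 1)
  if (nPos == 0L) stop("AUPRC undefined: no positive samples")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- fp <- 0
  prevRecall <- 0
  ap <- 0
  for (t in thr) {
    sel <- scores == t
    tp <- tp + sum(labels[sel] == 1)
    fp <- fp + sum(labels[sel] == 0)
    recall <- tp / nPos
    precision <- tp / (tp + fp)
    ap <- ap + (recall - prevRecall) * precision
    prevRecall <- recall
  }
  ap
}
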