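#' Confusion counts for a segmentation against ground truth
#'
#' Both masks are binarised by a set of positive labels (lesion pixels are
#' the positive class, background the negative class) and pixel counts of
#' true/false positives/negatives are accumulated.
#'
#' @param pred,truth Integer label matrices of identical shape.
#' @param positive Labels counted as lesion in `pred` and `truth`. The
#'   default `c(1, 2)` treats both the banded edge (1) and the lesion core
#'   (2) as positive, leaving background (0) negative.
#' @return Object of class `"confusion"`: list with integer counts `TP`,
#'   `FP`, `TN`, `FN` summing to the pixel count.
#' @export
confusion <- function(pred, truth, positive = c(1, 2)) {
  if (!identical(dim(as.matrix(pred)), dim(as.matrix(truth))))
    stop("'pred' and 'truth' must have identical dimensions")
  p <- pred %in% positive
  t <- truth %in% positive
  structure(list(TP = sum(p & t), FP = sum(p & !t),
                 TN = sum(!p & !t), FN = sum(!p & t)),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("confusion counts: TP %d, FP %d, TN %d, FN %d\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Segmentation scores from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, specificity `TN/(TN+FP)`, Jaccard
#' index `TP/(TP+FN+FP)` and Dice coefficient `2TP/(FP+2TP+FN)`. The
#' identity `Dice = 2 JA / (1 + JA)` holds whenever both are defined. A
#' ratio with zero denominator is returned as `NaN` with a warning naming
#' the score.
#'
#' @param counts A `"confusion"` object (or list with TP, FP, TN, FN).
#' @return Named numeric vector `c(Acc, SP, JA, Dice)`.
#' @examples
#' scores(list(TP = 3, FP = 1, TN = 4, FN = 2))  # 0.7, 0.8, 0.5, 2/3
#' @export
scores <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  if (tp + fp + tn + fn <= 0) stop("no pixels to score")
  ratio <- function(num, den, what) {
    if (den == 0) { warning(sprintf("%s undefined: zero denominator", what)); NaN }
    else num / den
  }
  c(Acc  = ratio(tp + tn, tp + tn + fp + fn, "Acc"),
    SP   = ratio(tn, tn + fp, "SP"),
    JA   = ratio(tp, tp + fn + fp, "JA"),
    Dice = ratio(2 * tp, fp + 2 * tp + fn, "Dice"))
}

#' Score a predicted mask against ground truth
#'
#' Convenience wrapper: [confusion()] then [scores()].
#'
#' @inheritParams confusion
#' @return Named numeric vector `c(Acc, SP, JA, Dice)`.
#' @export
evaluate_mask <- function(pred, truth, positive = c(1, 2)) {
  scores(confusion(pred, truth, positive))
}
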