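#' Confusion counts for a binary classifier
#'
#' Bundles the four cells of a 2x2 confusion matrix, with class 1 ("pain")
#' as the positive class.
#'
#' @param tp,tn,fp,fn Non-negative integer counts of true positives, true
#'   negatives, false positives and false negatives.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("confusion counts must be finite and non-negative")
  }
  if (any(counts != round(counts))) {
    stop("confusion counts must be whole numbers")
  }
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP=%d TN=%d FP=%d FN=%d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Tally a confusion matrix from hard predictions
#'
#' @param truth Binary vector (0/1) of reference labels, 1 = pain class.
#' @param predicted Binary vector (0/1) of predicted labels, same length.
#' @return A [confusion_counts()] object; the four counts sum to the vector
#'   length.
#' @export
confusion_from_predictions <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have the same length")
  }
  if (length(truth) < 1) stop("need at least one prediction")
  if (!all(truth %in% c(0, 1)) || !all(predicted %in% c(0, 1))) {
    stop("labels must be binary (0/1)")
  }
  confusion_counts(
    tp = sum(truth == 1 & predicted == 1),
    tn = sum(truth == 0 & predicted == 0),
    fp = sum(truth == 0 & predicted == 1),
    fn = sum(truth == 1 & predicted == 0)
  )
}

check_counts <- function(c) {
  if (!inherits(c, "confusion_counts")) stop("expected a confusion_counts object")
  if (c$tp + c$tn + c$fp + c$fn < 1) stop("confusion counts are all zero")
  c
}

# sensitivity/specificity with the zero-denominator-is-zero convention,
# so metrics stay defined on degenerate cross-validation folds
sensitivity_ <- function(c) if (c$tp + c$fn == 0) 0 else c$tp / (c$tp + c$fn)
specificity_ <- function(c) if (c$tn + c$fp == 0) 0 else c$tn / (c$tn + c$fp)

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, in `[-1, 1]`.
#' Returns 0 when any marginal factor of the denominator is zero.
#'
#' @param c A [confusion_counts()] object.
#' @return The MCC as a single number.
#' @export
mcc <- function(c) {
  c <- check_counts(c)
  # double arithmetic: the marginal product overflows 32-bit integers
  # already at a few hundred counts per cell
  den <- as.numeric(c$tp + c$fp) * as.numeric(c$tp + c$fn) *
    as.numeric(c$tn + c$fp) * as.numeric(c$tn + c$fn)
  if (den == 0) return(0)
  (as.numeric(c$tp) * c$tn - as.numeric(c$fp) * c$fn) / sqrt(den)
}

#' Geometric mean of sensitivity and specificity
#'
#' `sqrt(TP/(TP+FN) * TN/(TN+FP))`; a rate with zero denominator counts as 0.
#'
#' @inheritParams mcc
#' @return The G-mean in `[0, 1]`.
#' @export
gm <- function(c) {
  c <- check_counts(c)
  sqrt(sensitivity_(c) * specificity_(c))
}

#' F1 score
#'
#' Harmonic mean of precision `TP/(TP+FP)` and recall `TP/(TP+FN)`;
#' 0 when precision + recall is 0.
#'
#' @inheritParams mcc
#' @return The F1 score in `[0, 1]`.
#' @export
f1 <- function(c) {
  c <- check_counts(c)
  prec <- if (c$tp + c$fp == 0) 0 else c$tp / (c$tp + c$fp)
  rec <- sensitivity_(c)
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

#' Balanced accuracy
#'
#' Arithmetic mean of sensitivity and specificity, with the same
#' zero-denominator convention as [gm()].
#'
#' @inheritParams mcc
#' @return Balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(c) {
  c <- check_counts(c)
  (sensitivity_(c) + specificity_(c)) / 2
}

#' All four imbalance-robust metrics at once
#'
#' @inheritParams mcc
#' @return A named list with elements `mcc`, `gm`, `f1`, `ba`, of class
#'   `metric_set`.
#' @export
metric_set <- function(c) {
  c <- check_counts(c)
  structure(
    list(mcc = mcc(c), gm = gm(c), f1 = f1(c), ba = balanced_accuracy(c)),
    class = "metric_set"
  )
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("MCC=%.4f  GM=%.4f  F1=%.4f  BA=%.4f\n", x$mcc, x$gm, x$f1, x$ba))
  invisible(x)
}
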