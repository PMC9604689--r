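#' Confusion counts between two binary masks
#'
#' @param pred,truth Binary masks (logical or 0/1 arrays) of equal shape;
#'   1/TRUE marks brain.
#' @return An object of class \code{"confusion_counts"}: a list with
#'   integer fields \code{TP}, \code{FP}, \code{TN}, \code{FN}.
#' @export
confusion_counts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stop("`pred` and `truth` must have identical shape", call. = FALSE)
  p <- as.logical(pred); t <- as.logical(truth)
  structure(list(TP = sum(p & t), FP = sum(p & !t),
                 TN = sum(!p & !t), FN = sum(!p & t)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d (n = %d)\n",
              x$TP, x$FP, x$TN, x$FN, x$TP + x$FP + x$TN + x$FN))
  invisible(x)
}

#' Overlap and similarity metrics from confusion counts
#'
#' Evaluates the six standard voxel-overlap measures:
#' \deqn{JI = TP / (TP + FP + FN), \quad DSC = 2TP / (2TP + FP + FN),}
#' \deqn{Sens = TP / (TP + FN), \quad Spec = TN / (TN + FP),}
#' \deqn{Prec = TP / (TP + FP), \quad Acc = (TP + TN) / (TP+FP+TN+FN).}
#' A metric whose denominator is zero is reported as \code{NA} (undefined),
#' never as 0.
#'
#' @param counts A \code{confusion_counts} object (or a list with TP, FP,
#'   TN, FN).
#' @return An object of class \code{"similarity_report"}: a named numeric
#'   vector with elements \code{jaccard}, \code{dice}, \code{sensitivity},
#'   \code{specificity}, \code{accuracy}, \code{precision}.
#' @export
similarity_metrics <- function(counts) {
  with(counts, {
    if (min(TP, FP, TN, FN) < 0) stop("counts must be nonnegative", call. = FALSE)
    ratio <- function(num, den) if (den == 0) NA_real_ else num / den
    structure(c(jaccard = ratio(TP, TP + FP + FN),
                dice = ratio(2 * TP, 2 * TP + FP + FN),
                sensitivity = ratio(TP, TP + FN),
                specificity = ratio(TN, TN + FP),
                accuracy = ratio(TP + TN, TP + FP + TN + FN),
                precision = ratio(TP, TP + FP)),
              class = "similarity_report")
  })
}

#' @export
print.similarity_report <- function(x, digits = 4, ...) {
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Evaluate a segmentation against a ground truth
#'
#' Reduces both inputs to binary brain masks (label == \code{brain_label}
#' for 3-class arrays, nonzero for binary masks) and reports the six
#' overlap metrics.
#'
#' @param pred A \code{gubs} fit, a 3-class label array or a binary mask.
#' @param truth A 3-class label array or binary mask of the same shape.
#' @param brain_label Label coding brain in 3-class arrays (default 2).
#' @return A \code{similarity_report}.
#' @export
evaluate_segmentation <- function(pred, truth, brain_label = 2L) {
  to_mask <- function(x) {
    if (inherits(x, "gubs")) x <- x$labels
    if (is.logical(x)) return(x)
    if (max(x) > 1) x == brain_label else x > 0
  }
  similarity_metrics(confusion_counts(to_mask(pred), to_mask(truth)))
}
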