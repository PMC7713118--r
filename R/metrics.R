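#' Confusion counts between a predicted and a ground-truth mask
#'
#' Pixels included in the segmentation are the positives.
#'
#' @param pred,truth [binary_mask] objects or logical matrices of equal
#'   dimensions.
#' @return A `confusion_counts` list with fields `TP`, `FP`, `FN`, `TN`
#'   (summing to the pixel count).
#' @export
confusion <- function(pred, truth) {
  pred <- binary_mask(unclass(pred)); truth <- binary_mask(unclass(truth))
  if (!identical(dim(pred), dim(truth)))
    stop("mask dimensions differ")
  res <- list(TP = as.numeric(sum(pred & truth)),
              FP = as.numeric(sum(pred & !truth)),
              FN = as.numeric(sum(!pred & truth)),
              TN = as.numeric(sum(!pred & !truth)))
  class(res) <- "confusion_counts"
  res
}

metric_or_zero <- function(num, den) {
  if (den == 0) structure(0, degenerate = TRUE) else num / den
}

#' Binary segmentation metrics
#'
#' `accuracy()` is (TP+TN)/(TP+TN+FP+FN); `dice()` is the Sorensen-Dice
#' coefficient 2TP/(2TP+FP+FN); `inclusion()` is the inclusion score
#' (recall) TP/(TP+FN); `mcc()` is the Matthews correlation coefficient
#' with the standard square-root denominator
#' \eqn{(TP\,TN - FP\,FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}, which is
#' what keeps the stated range \[-1, 1\] (the unrooted product denominator
#' sometimes seen in print contradicts that range; it is available via
#' `rooted = FALSE`). Degenerate denominators return 0 carrying attribute
#' `degenerate = TRUE`.
#'
#' @param counts a `confusion_counts` object (or list with TP/FP/FN/TN).
#' @param rooted use the square-root MCC denominator (default TRUE).
#' @return A single number.
#' @examples
#' cc <- list(TP = 2, FP = 1, FN = 1, TN = 6)
#' c(accuracy(cc), dice(cc), inclusion(cc), mcc(cc))
#' @export
accuracy <- function(counts) {
  with(counts, metric_or_zero(TP + TN, TP + TN + FP + FN))
}

#' @rdname accuracy
#' @export
dice <- function(counts) {
  with(counts, metric_or_zero(2 * TP, 2 * TP + FP + FN))
}

#' @rdname accuracy
#' @export
inclusion <- function(counts) {
  with(counts, metric_or_zero(TP, TP + FN))
}

#' @rdname accuracy
#' @export
mcc <- function(counts, rooted = TRUE) {
  den <- with(counts, (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  num <- with(counts, TP * TN - FP * FN)
  if (den == 0) return(structure(0, degenerate = TRUE))
  if (rooted) num / sqrt(den) else num / den
}

#' Evaluate one predicted mask against a truth mask
#'
#' @param pred,truth masks as in [confusion()].
#' @return One-row data frame with the four metrics.
#' @export
evaluate_mask <- function(pred, truth) {
  cc <- confusion(pred, truth)
  data.frame(accuracy = as.numeric(accuracy(cc)),
             dice = as.numeric(dice(cc)),
             mcc = as.numeric(mcc(cc)),
             inclusion = as.numeric(inclusion(cc)))
}

#' Batch evaluation of (prediction, truth) pairs
#'
#' Computes the four metrics for every pair and appends per-group means,
#' in the shape of a per-method summary table.
#'
#' @param pairs list of `list(pred = , truth = )` mask pairs.
#' @param group label attached to all rows (e.g. the method name).
#' @return A list with `per_image` (data frame, one row per pair) and
#'   `summary` (one row of group means).
#' @export
batch_evaluate <- function(pairs, group = "group") {
  if (!length(pairs)) stop("no mask pairs supplied")
  rows <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    r <- evaluate_mask(pairs[[i]]$pred, pairs[[i]]$truth)
    cbind(data.frame(group = group, image = i), r)
  }))
  means <- colMeans(rows[, c("accuracy", "dice", "mcc", "inclusion")])
  summary <- cbind(data.frame(group = group, n = length(pairs)),
                   as.data.frame(as.list(means)))
  list(per_image = rows, summary = summary)
}
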