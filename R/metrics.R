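# ---- segmentation evaluation -----------------------------------------------
#
# Confusion-matrix convention: counts[i+1, j+1] = number of pixels annotated
# class i and predicted class j; row sums are the ground-truth class totals
# G_i. Metrics follow the standard definitions: pixel accuracy = trace /
# total; mean class accuracy = mean of per-class recall P_ii / G_i; mean
# IoU = mean of P_ii / (TP + FP + FN). The printed variant of the mean-IoU
# denominator (G_i + sum_{j != i} P_{i,j}, i.e. re-adding false negatives
# instead of false positives) is available via `as_printed = TRUE`.

#' Pixel-wise confusion matrix between two label maps
#'
#' Accumulate over several image pairs by adding the returned matrices.
#'
#' @param gt,pred [msl_labelmap]s (or integer matrices in 0..3) of
#'   identical shape.
#' @return 4 x 4 integer matrix of class `msl_confusion`; rows = annotated
#'   class, columns = predicted class.
#' @export
confusion <- function(gt, pred) {
  g <- unclass(gt); p <- unclass(pred)
  check_same_shape(g, p, "label maps")
  if (any(g < 0 | g > 3) || any(p < 0 | p > 3))
    stop("class ids must lie in 0..3", call. = FALSE)
  cm <- matrix(tabulate(as.vector(g) * 4L + as.vector(p) + 1L, nbins = 16L),
               4L, 4L, byrow = TRUE)
  dimnames(cm) <- list(annotated = msl_classes(), predicted = msl_classes())
  structure(cm, class = c("msl_confusion", class(cm)))
}

#' Pixel accuracy from a confusion matrix
#'
#' @param cm A 4 x 4 confusion matrix (annotated rows, predicted columns).
#' @return Fraction of correctly predicted pixels.
#' @export
pixel_accuracy <- function(cm) {
  tot <- sum(cm)
  if (tot == 0) stop("empty confusion matrix", call. = FALSE)
  sum(diag(cm)) / tot
}

#' Mean class accuracy (mean per-class recall)
#'
#' @inheritParams pixel_accuracy
#' @param strict_quarter If `TRUE`, always average over all 4 classes
#'   (absent classes contribute 0); default averages only over classes
#'   present in the ground truth.
#' @return Mean recall.
#' @export
mean_class_accuracy <- function(cm, strict_quarter = FALSE) {
  G <- rowSums(cm)
  present <- G > 0
  if (!any(present)) stop("no class present in ground truth", call. = FALSE)
  rec <- ifelse(present, diag(cm) / pmax(G, 1), 0)
  if (strict_quarter) sum(rec) / 4 else mean(rec[present])
}

#' Mean intersection-over-union
#'
#' Default: per-class IoU = TP / (TP + FP + FN), averaged over classes
#' present in ground truth or prediction. `as_printed = TRUE` uses the
#' literal denominator G_i + sum_{j != i} P_{i,j} (which re-adds false
#' negatives and ignores false positives); `strict_quarter` averages over
#' all four classes regardless of presence.
#'
#' @inheritParams mean_class_accuracy
#' @param as_printed Use the literal printed denominator.
#' @return Mean IoU.
#' @export
mean_iou <- function(cm, as_printed = FALSE, strict_quarter = FALSE) {
  tp <- diag(cm)
  G <- rowSums(cm)       # TP + FN
  P <- colSums(cm)       # TP + FP
  if (as_printed) {
    den <- G + (G - tp)  # G_i + sum_{j != i} P_{i,j}
    present <- G > 0
  } else {
    den <- G + P - tp    # TP + FP + FN
    present <- (G + P) > 0
  }
  if (!any(present)) stop("no class present", call. = FALSE)
  iou <- ifelse(present, tp / pmax(den, 1), 0)
  if (strict_quarter) sum(iou) / 4 else mean(iou[present])
}

#' Evaluate predictions against ground truth
#'
#' Accumulates one confusion matrix over all pairs and reports the three
#' standard metrics plus per-class recall and IoU.
#'
#' @param gt_list,pred_list Lists of [msl_labelmap]s, matched by position.
#' @param as_printed,strict_quarter Passed to [mean_iou()] /
#'   [mean_class_accuracy()].
#' @return List of class `msl_eval`: `confusion`, `pixel_accuracy`,
#'   `mean_class_accuracy`, `mean_iou`, `per_class` data frame.
#' @export
evaluate_segmentation <- function(gt_list, pred_list, as_printed = FALSE,
                                  strict_quarter = FALSE) {
  stopifnot(length(gt_list) == length(pred_list), length(gt_list) > 0)
  cm <- Reduce(`+`, Map(confusion, gt_list, pred_list))
  tp <- diag(cm); G <- rowSums(cm); P <- colSums(cm)
  per_class <- data.frame(
    class = msl_classes(),
    gt_pixels = as.integer(G),
    recall = ifelse(G > 0, tp / pmax(G, 1), NA_real_),
    iou = ifelse(G + P > 0, tp / pmax(G + P - tp, 1), NA_real_))
  structure(list(
    confusion = cm,
    pixel_accuracy = pixel_accuracy(cm),
    mean_class_accuracy = mean_class_accuracy(cm, strict_quarter),
    mean_iou = mean_iou(cm, as_printed, strict_quarter),
    per_class = per_class), class = "msl_eval")
}

#' @export
print.msl_eval <- function(x, ...) {
  cat(sprintf("pixel accuracy      %.4f\n", x$pixel_accuracy))
  cat(sprintf("mean class accuracy %.4f\n", x$mean_class_accuracy))
  cat(sprintf("mean IoU            %.4f\n", x$mean_iou))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}
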