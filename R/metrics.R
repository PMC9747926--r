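# Evaluation: blob-level segmentation metrics, image-level
# classification metrics, blob-to-ground-truth matching and the
# large-hemorrhage subset rule.

#' Confusion counts
#'
#' @param tp,tn,fp,fn nonnegative counts.
#' @param level \code{"blob"} (candidate level) or \code{"image"}.
#' @return object of class \code{confusion_counts}.
#' @export
confusion_counts <- function(tp, tn, fp, fn, level = c("blob", "image")) {
  level <- match.arg(level)
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn, level = level),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("%s-level confusion counts: TP=%g TN=%g FP=%g FN=%g\n",
              x$level, x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

.safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' F1 measure from precision and recall
#'
#' Harmonic mean \eqn{2pr/(p+r)}. Scale-invariant, so it accepts inputs
#' on either the \eqn{[0, 1]} or the percentage scale and reports on the
#' same scale.
#'
#' @param precision,recall numeric vectors on a common scale.
#' @return F1 on the same scale (0 where both inputs are 0).
#' @export
f1_score <- function(precision, recall) {
  out <- 2 * precision * recall / (precision + recall)
  out[precision + recall == 0] <- 0
  out
}

#' Blob-level segmentation metrics
#'
#' From blob confusion counts computes recall \eqn{TP/(TP+FN)}, precision
#' \eqn{TP/(TP+FP)}, their harmonic mean F1, and
#' \eqn{IoU = TP/(TP+FN+FP)}. Any 0/0 ratio is reported as 0 and the
#' metric name recorded in the \code{degenerate} field, so batch
#' evaluation never aborts. The field \code{candidate_accuracy},
#' \eqn{(TP+TN)/(TP+TN+FP+FN)}, is the overall fraction of correctly
#' handled candidates and is reported separately from recall.
#'
#' @param counts \code{confusion_counts} object.
#' @return object of class \code{segmentation_report} with fields
#'   \code{recall}, \code{precision}, \code{f1}, \code{iou},
#'   \code{candidate_accuracy} (each in \eqn{[0, 1]}), \code{degenerate}
#'   (character vector) and the input counts.
#' @export
segmentation_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  c_ <- counts
  vals <- list(recall = .safe_div(c_$tp, c_$tp + c_$fn),
               precision = .safe_div(c_$tp, c_$tp + c_$fp),
               iou = .safe_div(c_$tp, c_$tp + c_$fn + c_$fp),
               candidate_accuracy = .safe_div(c_$tp + c_$tn,
                                              c_$tp + c_$tn + c_$fp + c_$fn))
  degenerate <- names(vals)[vapply(vals, is.na, logical(1))]
  vals <- lapply(vals, function(v) if (is.na(v)) 0 else v)
  if (is.na(.safe_div(1, vals$precision + vals$recall)) ||
      (vals$precision + vals$recall) == 0) {
    f1 <- 0
    degenerate <- c(degenerate, "f1")
  } else {
    f1 <- f1_score(vals$precision, vals$recall)
  }
  structure(list(recall = vals$recall, precision = vals$precision,
                 f1 = f1, iou = vals$iou,
                 candidate_accuracy = vals$candidate_accuracy,
                 degenerate = degenerate, counts = counts),
            class = "segmentation_report")
}

#' @export
print.segmentation_report <- function(x, ...) {
  cat("blob-level segmentation metrics (%):\n")
  cat(sprintf("  recall %.2f  precision %.2f  F1 %.2f  IoU %.2f\n",
              100 * x$recall, 100 * x$precision, 100 * x$f1, 100 * x$iou))
  if (length(x$degenerate))
    cat("  degenerate (0/0, reported as 0):",
        paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' Image-level classification metrics
#'
#' Sensitivity \eqn{TP/(TP+FN)}, specificity \eqn{TN/(TN+FP)}, positive
#' predictive value \eqn{TP/(TP+FP)} and accuracy
#' \eqn{(TP+TN)/(TP+TN+FP+FN)} from image-level confusion counts.
#' Degenerate 0/0 ratios are reported as 0 with a flag, as in
#' [segmentation_metrics()].
#'
#' @param counts \code{confusion_counts} object.
#' @return object of class \code{classification_report} with fields
#'   \code{sensitivity}, \code{specificity}, \code{ppv}, \code{accuracy}
#'   (each in \eqn{[0, 1]}) and \code{degenerate}.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  vals <- list(sensitivity = .safe_div(counts$tp, counts$tp + counts$fn),
               specificity = .safe_div(counts$tn, counts$tn + counts$fp),
               ppv = .safe_div(counts$tp, counts$tp + counts$fp),
               accuracy = .safe_div(counts$tp + counts$tn,
                                    counts$tp + counts$tn +
                                      counts$fp + counts$fn))
  degenerate <- names(vals)[vapply(vals, is.na, logical(1))]
  vals <- lapply(vals, function(v) if (is.na(v)) 0 else v)
  structure(c(vals, list(degenerate = degenerate, counts = counts)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("image-level classification metrics (%):\n")
  cat(sprintf("  sensitivity %.2f  specificity %.2f  PPV %.2f  accuracy %.2f\n",
              100 * x$sensitivity, 100 * x$specificity, 100 * x$ppv,
              100 * x$accuracy))
  if (length(x$degenerate))
    cat("  degenerate (0/0, reported as 0):",
        paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' Match candidate blobs against a ground-truth mask
#'
#' A candidate is ground-truth positive when at least \code{overlap} of
#' its pixels fall inside the mask. TP are positive candidates classified
#' hemorrhagic, FP negative candidates classified hemorrhagic, TN
#' negative candidates classified nonhemorrhagic; FN counts positive
#' candidates classified nonhemorrhagic plus every ground-truth connected
#' component touched by no candidate at all (a lesion the candidate
#' generator missed entirely).
#'
#' @param blobs \code{blob_set} of candidates.
#' @param predicted_labels factor or character vector, one label per blob.
#' @param gt_mask logical ground-truth hemorrhage mask, same shape as the
#'   image the blobs came from.
#' @param overlap matching fraction (default 0.5).
#' @return \code{confusion_counts} at blob level.
#' @export
match_blobs <- function(blobs, predicted_labels, gt_mask, overlap = 0.5) {
  stopifnot(inherits(blobs, "blob_set"), is.logical(gt_mask),
            is.matrix(gt_mask))
  dm <- attr(blobs, "img_dim")
  if (!is.null(dm) && !all(dim(gt_mask) == dm))
    stop("ground-truth mask shape does not match the blobs' image shape")
  predicted_labels <- as.character(predicted_labels)
  if (length(predicted_labels) != nrow(blobs))
    stop("one predicted label per blob required")
  is_hem <- predicted_labels == "hemorrhagic"
  frac <- vapply(blobs$pixels,
                 function(px) if (length(px)) mean(gt_mask[px]) else 0,
                 numeric(1))
  gt_pos <- frac >= overlap
  tp <- sum(gt_pos & is_hem)
  fp <- sum(!gt_pos & is_hem)
  tn <- sum(!gt_pos & !is_hem)
  fn <- sum(gt_pos & !is_hem)
  glab <- .label8(gt_mask)
  ncomp <- max(glab)
  if (ncomp > 0L) {
    touched <- unique(glab[unlist(blobs$pixels)])
    touched <- touched[touched > 0L]
    fn <- fn + (ncomp - length(touched))
  }
  confusion_counts(tp, tn, fp, fn, level = "blob")
}

#' Pixel-level confusion counts of a predicted mask
#'
#' Convenience for pixelwise recall/precision/IoU of a segmentation mask
#' against ground truth (used e.g. to compare single-pass thresholding
#' with the region-growing result).
#'
#' @param pred_mask,gt_mask logical matrices of one shape.
#' @return \code{confusion_counts} (level \code{"blob"}, counting pixels).
#' @export
pixel_confusion <- function(pred_mask, gt_mask) {
  stopifnot(is.logical(pred_mask), is.logical(gt_mask),
            all(dim(pred_mask) == dim(gt_mask)))
  confusion_counts(sum(pred_mask & gt_mask), sum(!pred_mask & !gt_mask),
                   sum(pred_mask & !gt_mask), sum(!pred_mask & gt_mask),
                   level = "blob")
}

#' Large-hemorrhage rule
#'
#' A hemorrhage counts as large when the ratio of hemorrhagic area to the
#' circular retinal field-of-view area is strictly greater than
#' \code{threshold} (default 3.5\%).
#'
#' @param gt_mask logical hemorrhage mask.
#' @param retina_mask logical field-of-view mask of the same shape.
#' @param threshold area-ratio threshold.
#' @return \code{TRUE} iff the ratio exceeds the threshold strictly.
#' @export
is_large_hemorrhage <- function(gt_mask, retina_mask, threshold = 0.035) {
  stopifnot(is.logical(gt_mask), is.logical(retina_mask),
            all(dim(gt_mask) == dim(retina_mask)))
  denom <- sum(retina_mask)
  if (denom == 0) stop("retina mask is empty")
  sum(gt_mask) / denom > threshold
}

#' Estimate the retinal field-of-view mask
#'
#' The field of view is taken as the largest 8-connected region of pixels
#' whose summed RGB intensity exceeds a small floor, i.e. the circular
#' illuminated disc on the dark background.
#'
#' @param img RGB image array.
#' @param floor minimum summed intensity.
#' @return logical matrix.
#' @export
estimate_retina_mask <- function(img, floor = 0.05) {
  .assert_fundus(img)
  bright <- (img[, , 1L] + img[, , 2L] + img[, , 3L]) > floor
  lab <- .label8(bright)
  if (max(lab) == 0L) return(bright)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}
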