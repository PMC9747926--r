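# HSV feature extraction per candidate blob and SVM classification with
# stratified cross-validation; image-level decision rule.

.circular_mean <- function(h) {
  s <- mean(sin(2 * pi * h)); c <- mean(cos(2 * pi * h))
  if (abs(s) < 1e-12 && abs(c) < 1e-12) return(mean(h) %% 1)
  (atan2(s, c) / (2 * pi)) %% 1
}

#' Extract HSV features of a single blob
#'
#' Hemorrhages are rich in color with low saturation and low brightness,
#' so the mean hue, saturation and brightness of the blob's pixels on the
#' original (unenhanced) image are used as features. Hue is circular, so
#' its mean is the circular mean on the \eqn{[0, 1)} turn scale.
#'
#' @param pixels blob pixels: vector of linear indices, or a two-column
#'   (row, col) coordinate matrix.
#' @param img original RGB image array.
#' @return named numeric vector \code{h_mean}, \code{s_mean},
#'   \code{v_mean}, each in \eqn{[0, 1]}.
#' @export
extract_features <- function(pixels, img) {
  .assert_fundus(img)
  dm <- dim(img)[1:2]
  idx <- if (is.matrix(pixels)) .as_index(pixels, dm) else as.integer(pixels)
  if (length(idx) == 0L) stop("cannot extract features of an empty blob")
  if (any(idx < 1L | idx > prod(dm))) stop("blob pixels outside the image")
  planes <- img2hsv(img)
  c(h_mean = .circular_mean(planes$H[idx]),
    s_mean = mean(planes$S[idx]),
    v_mean = mean(planes$V[idx]))
}

#' Extract HSV features for every blob in a blob set
#'
#' @param blobs \code{blob_set} from [label_blobs()].
#' @param img original RGB image array.
#' @return data frame with one row per blob: \code{blob_id},
#'   \code{h_mean}, \code{s_mean}, \code{v_mean}.
#' @export
blob_features <- function(blobs, img) {
  stopifnot(inherits(blobs, "blob_set"))
  .assert_fundus(img)
  planes <- img2hsv(img)
  rows <- lapply(seq_len(nrow(blobs)), function(i) {
    idx <- blobs$pixels[[i]]
    data.frame(blob_id = blobs$blob_id[i],
               h_mean = .circular_mean(planes$H[idx]),
               s_mean = mean(planes$S[idx]),
               v_mean = mean(planes$V[idx]))
  })
  if (!length(rows))
    return(data.frame(blob_id = integer(0), h_mean = numeric(0),
                      s_mean = numeric(0), v_mean = numeric(0)))
  do.call(rbind, rows)
}

# Hue is circular with hemorrhage hues clustered near the 0/1 wrap
# point (red), so the classifier sees hue as the (sin, cos) pair.
.encode_features <- function(features) {
  f <- as.data.frame(features)
  stopifnot(all(c("h_mean", "s_mean", "v_mean") %in% names(f)))
  cbind(h_sin = sin(2 * pi * f$h_mean), h_cos = cos(2 * pi * f$h_mean),
        s = f$s_mean, v = f$v_mean)
}

.blob_levels <- c("nonhemorrhagic", "hemorrhagic")

.stratified_folds <- function(labels, folds, seed) {
  fold <- integer(length(labels))
  .with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

#' Train and evaluate the blob classifier with stratified cross-validation
#'
#' Fits a radial-kernel SVM on blob HSV features under stratified k-fold
#' cross-validation: every blob is predicted by the model trained on the
#' folds that exclude it, so held-out accuracy is leakage-free. Features
#' are standardized inside each training fold (the SVM scales on its
#' training data only). A final model trained on all blobs is returned
#' for deployment on new images.
#'
#' @param features data frame with columns \code{h_mean}, \code{s_mean},
#'   \code{v_mean} (one row per blob), e.g. from [blob_features()].
#' @param labels factor or character vector, values \code{"hemorrhagic"}
#'   or \code{"nonhemorrhagic"}; both classes must be present.
#' @param folds number of folds.
#' @param seed RNG seed for fold assignment.
#' @param cost SVM soft-margin cost.
#' @param gamma RBF kernel width; default \eqn{1/d} on the standardized
#'   features (i.e. \eqn{1/(d \sigma^2)} with unit fold variance).
#' @return object of class \code{hemseg_cv}: list with per-blob held-out
#'   \code{predictions}, \code{fold} assignments, held-out
#'   \code{accuracy}, the per-fold accuracies and the final \code{model}.
#' @export
crossval_train_eval <- function(features, labels, folds = 5L, seed = 1L,
                                cost = 1, gamma = NULL) {
  x <- .encode_features(features)
  labels <- factor(as.character(labels), levels = .blob_levels)
  if (anyNA(labels))
    stop("labels must be 'hemorrhagic' or 'nonhemorrhagic'")
  if (nlevels(droplevels(labels)) < 2L)
    stop("both classes must be present to train the classifier")
  n <- nrow(x)
  if (n < folds)
    stop("need at least ", folds, " blobs for ", folds, "-fold CV, got ", n)
  fold <- .stratified_folds(labels, folds, seed)
  gamma <- gamma %||% (1 / ncol(x))
  preds <- factor(rep(NA_character_, n), levels = .blob_levels)
  fold_acc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- e1071::svm(x[tr, , drop = FALSE], labels[tr],
                      kernel = "radial", cost = cost, gamma = gamma,
                      scale = TRUE)
    p <- predict(fit, x[!tr, , drop = FALSE])
    preds[!tr] <- p
    fold_acc[f] <- mean(p == labels[!tr])
  }
  model <- e1071::svm(x, labels, kernel = "radial", cost = cost,
                      gamma = gamma, scale = TRUE)
  structure(list(predictions = preds, fold = fold, labels = labels,
                 accuracy = mean(preds == labels), fold_accuracy = fold_acc,
                 folds = folds, seed = seed, cost = cost, gamma = gamma,
                 model = model),
            class = "hemseg_cv")
}

#' @export
print.hemseg_cv <- function(x, ...) {
  cat(sprintf("SVM blob classifier, %d-fold stratified CV on %d blobs\n",
              x$folds, length(x$labels)))
  cat(sprintf("  held-out accuracy: %.4f\n", x$accuracy))
  cat(sprintf("  per-fold: %s\n",
              paste(sprintf("%.3f", x$fold_accuracy), collapse = " ")))
  invisible(x)
}

#' Predict labels for new blobs
#'
#' @param object \code{hemseg_cv} object.
#' @param features data frame with \code{h_mean}, \code{s_mean},
#'   \code{v_mean} columns.
#' @param ... unused.
#' @return factor of predicted labels.
#' @export
predict.hemseg_cv <- function(object, features, ...) {
  x <- .encode_features(features)
  if (nrow(x) == 0L) return(factor(character(0), levels = .blob_levels))
  factor(as.character(predict(object$model, x)), levels = .blob_levels)
}

#' Image-level decision from blob predictions
#'
#' An image is positive when at least one candidate blob is classified
#' hemorrhagic; an image with no candidates, or only nonhemorrhagic
#' candidates, is negative.
#'
#' @param predicted_labels factor or character vector of blob predictions
#'   (may be empty).
#' @return \code{"positive"} or \code{"negative"}.
#' @export
classify_image <- function(predicted_labels) {
  if (any(as.character(predicted_labels) == "hemorrhagic")) "positive"
  else "negative"
}
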