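# Top-level driver: preprocess, segment, remove vessels, extract
# features and (optionally) classify, returning one classed result.

#' Run the hemorrhage segmentation pipeline on one image
#'
#' Executes the full candidate-generation pipeline: KMMRC + CLAHE +
#' average-filter preprocessing, iterative NICK-thresholding region
#' growing, connected-component labeling and ellipse axis-ratio vessel
#' removal, followed by HSV feature extraction on the original image.
#' When a trained classifier is supplied, candidates are labeled and the
#' image-level decision (any hemorrhagic blob means positive) is taken.
#'
#' @param img RGB image array in \eqn{[0, 1]} (see [read_image()]) or a
#'   \code{synthetic_scene}.
#' @param params [hemseg_params()] configuration.
#' @param classifier optional \code{hemseg_cv} object from
#'   [crossval_train_eval()].
#' @return object of class \code{hemseg}: list with the preprocessed
#'   \code{gray} plane, INRG \code{points} and growth diagnostics, the
#'   full and vessel-filtered blob tables, per-blob \code{features},
#'   optional \code{predictions} and \code{decision}, and a per-stage
#'   \code{log} of blob counts.
#' @seealso [segmentation_metrics()], [match_blobs()] for evaluation.
#' @export
hemseg <- function(img, params = hemseg_params(), classifier = NULL) {
  if (inherits(img, "synthetic_scene")) img <- img$image
  .assert_fundus(img)
  gray <- preprocess_fundus(img, params)
  seg <- inrg(gray, params$kappa, params$N, params$n_pass, params$delta,
              details = TRUE)
  # the dark background outside the circular field of view is trivially
  # "salient dark" to a local threshold; candidates are restricted to
  # the retinal disc
  fov <- estimate_retina_mask(img, params$retina_floor)
  blobs <- label_blobs(seg$points & fov, min_area = params$min_area)
  candidates <- remove_vessels(blobs, params$vessel_ratio)
  features <- blob_features(candidates, img)
  predictions <- NULL
  decision <- NULL
  if (!is.null(classifier)) {
    predictions <- predict(classifier, features)
    decision <- classify_image(predictions)
  }
  log <- data.frame(
    stage = c("inrg_pixels", "blobs", "after_vessel_removal"),
    count = c(sum(seg$points), nrow(blobs), nrow(candidates)))
  structure(list(image = img, gray = gray, fov = fov, points = seg$points,
                 inrg_sizes = seg$sizes, growth_rates = seg$growth_rates,
                 blobs = blobs, candidates = candidates,
                 features = features, predictions = predictions,
                 decision = decision, params = params, log = log),
            class = "hemseg")
}

#' Predicted hemorrhage mask of a pipeline result
#'
#' @param x \code{hemseg} object.
#' @param classified_only if \code{TRUE} (and predictions exist), only
#'   blobs classified hemorrhagic are rasterized; otherwise all
#'   candidates surviving vessel removal.
#' @return logical matrix.
#' @export
hemseg_mask <- function(x, classified_only = !is.null(x$predictions)) {
  stopifnot(inherits(x, "hemseg"))
  if (classified_only && !is.null(x$predictions)) {
    keep <- x$candidates[as.character(x$predictions) == "hemorrhagic", ,
                         drop = FALSE]
    class(keep) <- class(x$candidates)
    attr(keep, "img_dim") <- attr(x$candidates, "img_dim")
    blobs_to_mask(keep)
  } else {
    blobs_to_mask(x$candidates)
  }
}

#' @export
print.hemseg <- function(x, ...) {
  dm <- dim(x$image)
  cat(sprintf("hemseg result on a %dx%d image\n", dm[1], dm[2]))
  cat(sprintf("  INRG passes: %d, region pixels %s\n",
              length(x$inrg_sizes),
              paste(x$inrg_sizes, collapse = " -> ")))
  cat(sprintf("  blobs: %d segmented, %d after vessel removal\n",
              nrow(x$blobs), nrow(x$candidates)))
  if (!is.null(x$decision))
    cat(sprintf("  classified: %d hemorrhagic blob(s), image %s\n",
                sum(as.character(x$predictions) == "hemorrhagic"),
                x$decision))
  invisible(x)
}

#' @export
summary.hemseg <- function(object, ...) {
  print(object)
  if (nrow(object$candidates)) {
    cat("\ncandidate blobs:\n")
    df <- object$candidates
    df$pixels <- NULL
    df <- cbind(df, object$features[, c("h_mean", "s_mean", "v_mean")])
    if (!is.null(object$predictions)) df$predicted <- object$predictions
    print(head(df, 15), row.names = FALSE, digits = 3)
    if (nrow(df) > 15) cat("  ... and", nrow(df) - 15, "more\n")
  }
  invisible(object)
}

#' Plot a pipeline result
#'
#' Renders the original image with candidate blob outlines: candidates
#' classified hemorrhagic (or all candidates when no classifier was
#' applied) are drawn over the image.
#'
#' @param x \code{hemseg} object.
#' @param ... unused.
#' @export
plot.hemseg <- function(x, ...) {
  img <- x$image
  mask <- hemseg_mask(x)
  disp <- img
  r <- disp[, , 1]; g <- disp[, , 2]
  r[mask] <- 1; g[mask] <- 1
  disp[, , 1] <- r; disp[, , 2] <- g
  op <- graphics::par(mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  graphics::plot(c(0, 1), c(0, 1), type = "n", axes = FALSE,
                 xlab = "", ylab = "", asp = dim(img)[1] / dim(img)[2],
                 main = "hemseg candidates")
  graphics::rasterImage(grDevices::as.raster(aperm(disp, c(1, 2, 3))),
                        0, 0, 1, 1)
  invisible(x)
}

#' Evaluate a pipeline result against ground truth
#'
#' Computes blob-level confusion counts and segmentation metrics against
#' a hemorrhage mask. When the result carries no classifier predictions,
#' every candidate is treated as predicted hemorrhagic (pure
#' segmentation evaluation).
#'
#' @param x \code{hemseg} object.
#' @param gt_mask logical ground-truth hemorrhage mask.
#' @return list with \code{counts} (\code{confusion_counts}) and
#'   \code{segmentation} (\code{segmentation_report}).
#' @export
evaluate_hemseg <- function(x, gt_mask) {
  stopifnot(inherits(x, "hemseg"))
  labels <- if (!is.null(x$predictions)) as.character(x$predictions)
            else rep("hemorrhagic", nrow(x$candidates))
  counts <- match_blobs(x$candidates, labels, gt_mask,
                        overlap = x$params$match_overlap)
  list(counts = counts, segmentation = segmentation_metrics(counts))
}
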