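# Pipeline configuration: every tunable in one place, round-trippable
# through YAML for the command-line interface.

#' Pipeline parameters
#'
#' Collects every tunable of the segmentation pipeline. Defaults follow
#' the operating point of the method: \code{K = 5} brightness regions and
#' gain \code{beta = 1.5} for the multiregion contrast stretch;
#' NICK bias \code{kappa = -0.2} with an \code{N = 9025}-pixel (95 x 95)
#' window; at most \code{n_pass = 3} region-growing passes with
#' convergence constant \code{delta = 0.1}; vessels removed above ellipse
#' axis ratio \code{6.4}; a hemorrhage is "large" above 3.5\% of the
#' retinal disc area.
#'
#' @param K number of brightness regions for the K-means partition.
#' @param beta linear contrast gain applied within each region
#'   (\code{beta = 1} leaves brightness unchanged).
#' @param kmeans_seed seed for the K-means initialization.
#' @param clahe_clip CLAHE clip limit as a fraction of the tile histogram
#'   (0 disables the CLAHE stage).
#' @param clahe_tiles CLAHE tile grid \code{c(rows, cols)}.
#' @param clahe_bins number of histogram bins used by CLAHE.
#' @param filter_window odd side length of the average (box) filter
#'   (1 disables smoothing).
#' @param kappa NICK threshold bias; negative values push the threshold
#'   below the local mean. Values outside \eqn{[-0.2, -0.1]} are accepted
#'   with a warning.
#' @param N NICK window pixel count; must be the square of an odd side.
#' @param n_pass maximum number of thresholding passes of the region
#'   growing loop (\code{n_pass = 1} is plain NICK thresholding).
#' @param delta convergence constant: growing stops when the relative
#'   increase in region pixel count falls below \code{delta}.
#' @param vessel_ratio blobs with ellipse axis ratio strictly above this
#'   are discarded as vessels.
#' @param min_area minimum blob area in pixels (0 keeps all blobs).
#' @param match_overlap fraction of a candidate's pixels that must fall in
#'   the ground-truth mask for the candidate to count as truly positive.
#' @param large_ratio hemorrhage-to-retina area ratio above which a
#'   hemorrhage counts as large.
#' @param svm_cost SVM soft-margin cost.
#' @param cv_folds number of cross-validation folds.
#' @param cv_seed seed for fold assignment.
#' @param retina_floor minimum summed RGB intensity for a pixel to count
#'   as part of the retinal field of view.
#' @return object of class \code{hemseg_params} (a validated list).
#' @export
hemseg_params <- function(K = 5L, beta = 1.5, kmeans_seed = 42L,
                          clahe_clip = 0.01, clahe_tiles = c(8L, 8L),
                          clahe_bins = 256L, filter_window = 5L,
                          kappa = -0.2, N = 9025L,
                          n_pass = 3L, delta = 0.1,
                          vessel_ratio = 6.4, min_area = 0L,
                          match_overlap = 0.5, large_ratio = 0.035,
                          svm_cost = 1, cv_folds = 5L, cv_seed = 1L,
                          retina_floor = 0.05) {
  stopifnot(K >= 1, beta > 0, filter_window >= 1,
            filter_window %% 2 == 1, n_pass >= 1, delta > 0,
            vessel_ratio >= 1, min_area >= 0,
            match_overlap > 0, match_overlap <= 1,
            large_ratio > 0, svm_cost > 0, cv_folds >= 2)
  side <- sqrt(N)
  if (side != floor(side) || side %% 2 != 1)
    stop("N must be a perfect square of an odd side length, got ", N)
  if (kappa < -0.2 || kappa > -0.1)
    warning("kappa = ", kappa, " lies outside the usual [-0.2, -0.1] range")
  structure(list(K = as.integer(K), beta = beta,
                 kmeans_seed = as.integer(kmeans_seed),
                 clahe_clip = clahe_clip,
                 clahe_tiles = as.integer(clahe_tiles),
                 clahe_bins = as.integer(clahe_bins),
                 filter_window = as.integer(filter_window),
                 kappa = kappa, N = as.integer(N),
                 n_pass = as.integer(n_pass), delta = delta,
                 vessel_ratio = vessel_ratio,
                 min_area = as.integer(min_area),
                 match_overlap = match_overlap, large_ratio = large_ratio,
                 svm_cost = svm_cost, cv_folds = as.integer(cv_folds),
                 cv_seed = as.integer(cv_seed),
                 retina_floor = retina_floor),
            class = "hemseg_params")
}

#' @export
print.hemseg_params <- function(x, ...) {
  cat("hemseg pipeline parameters\n")
  cat(sprintf("  KMMRC:   K = %d, beta = %.3g (seed %d)\n",
              x$K, x$beta, x$kmeans_seed))
  cat(sprintf("  CLAHE:   clip = %.3g, tiles = %dx%d; average filter %dx%d\n",
              x$clahe_clip, x$clahe_tiles[1], x$clahe_tiles[2],
              x$filter_window, x$filter_window))
  cat(sprintf("  INRG:    kappa = %.3g, N = %d (%dx%d), n = %d, delta = %.3g\n",
              x$kappa, x$N, sqrt(x$N), sqrt(x$N), x$n_pass, x$delta))
  cat(sprintf("  Blobs:   vessel axis ratio > %.2g removed, min area %d\n",
              x$vessel_ratio, x$min_area))
  cat(sprintf("  SVM:     cost = %.3g, %d-fold CV (seed %d)\n",
              x$svm_cost, x$cv_folds, x$cv_seed))
  invisible(x)
}

#' Read pipeline parameters from a YAML file
#'
#' Keys absent from the file keep their defaults.
#'
#' @param path YAML file path.
#' @return \code{hemseg_params} object.
#' @export
params_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(hemseg_params))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown parameter(s) in ", path, ": ",
                        paste(bad, collapse = ", "))
  do.call(hemseg_params, vals)
}

#' Write pipeline parameters to a YAML file
#'
#' @param params \code{hemseg_params} object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
params_to_yaml <- function(params, path) {
  stopifnot(inherits(params, "hemseg_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
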