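# Candidate generation: NICK local adaptive thresholding, iterative
# region growing (INRG), connected-component labeling and ellipse
# axis-ratio vessel removal.

.nick_side <- function(N) {
  side <- sqrt(N)
  if (side != floor(side) || side %% 2 != 1)
    stop("N must be a perfect square of an odd side length, got ", N)
  as.integer(side)
}

#' NICK local adaptive thresholding
#'
#' Computes, for every pixel, the threshold
#' \deqn{\tau(x,y) = avg(x,y) + \kappa \sqrt{(\Sigma V^2(x,y) - avg^2(x,y)) / N}}
#' over the \code{N}-pixel square window centered on the pixel (borders
#' reflected), where \eqn{avg} is the window mean and \eqn{\Sigma V^2} the
#' window sum of squared intensities, and returns the set of pixels
#' strictly darker than their threshold. With negative \eqn{\kappa} the
#' threshold sits below the local mean, selecting locally salient dark
#' objects such as hemorrhages; on a constant image nothing passes.
#'
#' @param gray grayscale matrix in \eqn{[0, 1]}.
#' @param kappa threshold bias, conventionally in \eqn{[-0.2, -0.1]}.
#' @param N window pixel count, the square of an odd side (the default
#'   9025 is a 95 x 95 window).
#' @return logical matrix: \code{TRUE} where \eqn{V(x,y) < \tau(x,y)}.
#' @seealso [inrg()] for the iterative region-growing loop on top.
#' @export
nick_threshold <- function(gray, kappa = -0.2, N = 9025L) {
  .assert_gray(gray)
  side <- .nick_side(N)
  if (N > length(gray))
    stop("NICK window (", N, " pixels) larger than the image (",
         length(gray), " pixels)")
  r <- (side - 1L) %/% 2L
  if (r >= nrow(gray) || r >= ncol(gray))
    stop("NICK window side ", side, " does not fit the image extent ",
         nrow(gray), "x", ncol(gray))
  avg <- .box_mean(gray, side)
  sumsq <- .box_sum(gray^2, side)
  tau <- avg + kappa * sqrt(pmax(sumsq - avg^2, 0) / N)
  gray < tau
}

#' Average intensity over a point set
#'
#' @param gray grayscale matrix.
#' @param pts point set (logical mask or two-column coordinate matrix).
#' @return arithmetic mean of \code{gray} over the points.
#' @export
avg_green <- function(gray, pts) {
  .assert_gray(gray)
  idx <- .as_index(pts, dim(gray))
  if (length(idx) == 0L) stop("cannot average over an empty point set")
  mean(gray[idx])
}

#' Replace a point set with a constant intensity
#'
#' @param gray grayscale matrix.
#' @param pts point set (logical mask or two-column coordinate matrix).
#' @param value replacement intensity.
#' @return new grayscale matrix; pixels outside \code{pts} are untouched.
#' @export
replace_region <- function(gray, pts, value) {
  .assert_gray(gray)
  idx <- .as_index(pts, dim(gray))
  gray[idx] <- value
  gray
}

#' Iterative NICK-thresholding region growing (INRG)
#'
#' Extracts multishade dark blobs. The first pass is plain NICK
#' thresholding. Each subsequent pass replaces every connected blob of
#' the current region set with that blob's own average intensity in the
#' working image -- lifting the darkest shades toward the blob mean --
#' re-thresholds the modified image, and unions the result with the
#' current set. Growing stops after at most \code{n_pass - 1} growth
#' passes, or earlier when the relative increase in pixel count falls
#' below \code{delta}. The returned set is always a superset of the
#' single-pass result, and \code{n_pass = 1} is exactly
#' [nick_threshold()].
#'
#' @param gray preprocessed grayscale matrix (green-channel derived).
#' @param kappa,N NICK parameters, see [nick_threshold()].
#' @param n_pass maximum number of thresholding passes (\eqn{\ge 1}).
#' @param delta convergence constant for the relative growth rate.
#' @param details if \code{TRUE}, return a list with the final mask, the
#'   per-pass masks and pixel counts, and the growth rates.
#' @return logical matrix of candidate pixels (or a detail list).
#' @export
inrg <- function(gray, kappa = -0.2, N = 9025L, n_pass = 3L, delta = 0.1,
                 details = FALSE) {
  stopifnot(n_pass >= 1, delta > 0)
  A <- nick_threshold(gray, kappa, N)
  history <- list(A)
  rates <- numeric(0)
  work <- gray
  if (any(A) && n_pass >= 2L) {
    for (t in seq_len(n_pass - 1L)) {
      lab <- .label8(A)
      idx <- which(A)
      blob_mean <- tapply(work[idx], lab[idx], mean)
      work[idx] <- blob_mean[as.character(lab[idx])]
      grown <- A | nick_threshold(work, kappa, N)
      rate <- (sum(grown) - sum(A)) / sum(A)
      rates <- c(rates, rate)
      A <- grown
      history[[length(history) + 1L]] <- A
      if (rate < delta) break
    }
  }
  if (details)
    return(list(points = A, history = history,
                sizes = vapply(history, sum, numeric(1)),
                growth_rates = rates))
  A
}

#' Label candidate blobs
#'
#' 8-connected component labeling of a point set, with per-blob area,
#' centroid and moment-fitted ellipse axis lengths. The ellipse comes
#' from the eigenvalues of the pixel-coordinate covariance (with the 1/12
#' per-pixel correction), axis length \eqn{4\sqrt{\lambda}}; the minor
#' axis is floored at one pixel before forming the ratio, so a
#' single-pixel blob has axis ratio 1.
#'
#' @param pts point set (logical mask or two-column coordinate matrix).
#' @param dim image dimensions \code{c(rows, cols)}; required when
#'   \code{pts} is a coordinate matrix.
#' @param min_area drop blobs smaller than this many pixels.
#' @return data frame of class \code{blob_set} with columns
#'   \code{blob_id}, \code{area}, \code{centroid_row}, \code{centroid_col},
#'   \code{major_axis}, \code{minor_axis}, \code{axis_ratio} and a list
#'   column \code{pixels} of linear pixel indices; the image dimension is
#'   kept in attribute \code{"img_dim"}.
#' @export
label_blobs <- function(pts, dim = NULL, min_area = 0L) {
  if (is.logical(pts) && is.matrix(pts)) dim <- base::dim(pts)
  if (is.null(dim)) stop("image dimensions required")
  mask <- points_to_mask(pts, dim)
  lab <- .label8(mask)
  nb <- max(lab)
  empty <- data.frame(blob_id = integer(0), area = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      major_axis = numeric(0), minor_axis = numeric(0),
                      axis_ratio = numeric(0))
  if (nb == 0L) {
    empty$pixels <- I(list())
    attr(empty, "img_dim") <- dim
    class(empty) <- c("blob_set", "data.frame")
    return(empty)
  }
  idx <- which(mask)
  groups <- split(idx, lab[idx])
  rows <- lapply(seq_len(nb), function(i) {
    px <- groups[[i]]
    r <- ((px - 1L) %% dim[1L]) + 1L
    cl <- ((px - 1L) %/% dim[1L]) + 1L
    ax <- .ellipse_axes(r, cl)
    data.frame(blob_id = i, area = length(px),
               centroid_row = ax[["centroid_row"]],
               centroid_col = ax[["centroid_col"]],
               major_axis = ax[["major"]], minor_axis = ax[["minor"]],
               axis_ratio = ax[["major"]] / max(ax[["minor"]], 1))
  })
  out <- do.call(rbind, rows)
  out$pixels <- I(unname(groups))
  if (min_area > 0L) {
    out <- out[out$area >= min_area, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "img_dim") <- dim
  class(out) <- c("blob_set", "data.frame")
  out
}

#' Remove elongated blobs as vessels
#'
#' Long thin blobs are usually blood vessels; any blob whose fitted
#' ellipse axis ratio is strictly greater than \code{ratio} is discarded.
#' Surviving blobs are returned unaltered; the removed ones are kept in
#' attribute \code{"removed"}.
#'
#' @param blobs \code{blob_set} from [label_blobs()].
#' @param ratio axis-ratio threshold (default 6.4). A blob with ratio
#'   exactly equal to the threshold is kept.
#' @return filtered \code{blob_set}.
#' @export
remove_vessels <- function(blobs, ratio = 6.4) {
  stopifnot(inherits(blobs, "blob_set"))
  keep <- blobs$axis_ratio <= ratio
  out <- blobs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "img_dim") <- attr(blobs, "img_dim")
  attr(out, "removed") <- blobs$blob_id[!keep]
  class(out) <- c("blob_set", "data.frame")
  out
}

#' Rasterize a blob set to a binary mask
#'
#' @param blobs \code{blob_set}.
#' @return logical matrix covering the blobs' pixels.
#' @export
blobs_to_mask <- function(blobs) {
  stopifnot(inherits(blobs, "blob_set"))
  dm <- attr(blobs, "img_dim")
  m <- matrix(FALSE, dm[1L], dm[2L])
  m[unlist(blobs$pixels)] <- TRUE
  m
}
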