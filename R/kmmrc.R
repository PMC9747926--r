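# Preprocessing: K-means multiregion contrast enhancement (KMMRC),
# global CLAHE and average-filter smoothing.

# Deterministic k-means++ seeding over the unique brightness values,
# weighted by their pixel counts. Returning unique values guarantees
# distinct starting centers.
.kmeanspp_centers <- function(v, K) {
  tab <- table(v)
  u <- as.numeric(names(tab))
  w <- as.numeric(tab)
  centers <- numeric(K)
  centers[1L] <- u[sample.int(length(u), 1L, prob = w)]
  d2 <- (u - centers[1L])^2
  k <- 1L
  while (k < K) {
    k <- k + 1L
    pr <- w * d2
    centers[k] <- u[sample.int(length(u), 1L, prob = pr)]
    d2 <- pmin(d2, (u - centers[k])^2)
  }
  centers
}

#' Partition the brightness plane into K intensity regions
#'
#' One-dimensional K-means on pixel brightness. Regions are relabeled in
#' order of increasing mean brightness, so region 1 is always the darkest.
#' Clustering is on intensity alone (no spatial coordinates), so a region
#' may be spatially disconnected; jointly the regions partition the image.
#'
#' @param V brightness plane (numeric matrix in \eqn{[0, 1]}).
#' @param K requested number of regions. If the plane holds fewer distinct
#'   values than \code{K}, the count is reduced to that number with a
#'   warning.
#' @param seed RNG seed for the k-means++ initialization; results are
#'   deterministic for a fixed seed.
#' @return object of class \code{brightness_partition}: list with
#'   \code{labels} (integer matrix, values 1..K), \code{region_means}
#'   (mean brightness per region), \code{sizes} and \code{K}.
#' @export
kmeans_segment_brightness <- function(V, K = 5L, seed = 42L) {
  .assert_gray(V)
  stopifnot(K >= 1)
  v <- as.vector(V)
  nu <- length(unique(v))
  if (nu < K) {
    warning("only ", nu, " distinct brightness values; reducing K from ",
            K, " to ", nu)
    K <- nu
  }
  K <- as.integer(K)
  if (K == 1L) {
    labels <- matrix(1L, nrow(V), ncol(V))
    return(structure(list(labels = labels, region_means = mean(v),
                          sizes = length(v), K = 1L),
                     class = "brightness_partition"))
  }
  fit <- .with_seed(seed, {
    centers <- .kmeanspp_centers(v, K)
    kmeans(v, centers = matrix(sort(centers), ncol = 1L), iter.max = 300L)
  })
  ord <- order(fit$centers[, 1L])
  remap <- integer(K); remap[ord] <- seq_len(K)
  lab <- remap[fit$cluster]
  means <- vapply(seq_len(K), function(i) mean(v[lab == i]), numeric(1))
  structure(list(labels = matrix(as.integer(lab), nrow(V), ncol(V)),
                 region_means = means,
                 sizes = tabulate(lab, K), K = K),
            class = "brightness_partition")
}

#' @export
print.brightness_partition <- function(x, ...) {
  cat("brightness partition:", x$K, "regions over",
      length(x$labels), "pixels\n")
  print(data.frame(region = seq_len(x$K),
                   mean_brightness = round(x$region_means, 4),
                   pixels = x$sizes), row.names = FALSE)
  invisible(x)
}

#' K-means multiregion contrast enhancement (KMMRC)
#'
#' Corrects uneven illumination by stretching contrast separately within
#' brightness regions. The image is decomposed into HSV planes, the
#' brightness plane is partitioned into \code{K} intensity regions, and
#' within region \eqn{i} with mean \eqn{M_i} each brightness value is
#' mapped to \eqn{M_i + \beta (V - M_i)}, clipped to \eqn{[0, 1]}. Hue and
#' saturation are left untouched and the image is rebuilt from the
#' modified brightness plane.
#'
#' @param img RGB image array in \eqn{[0, 1]}.
#' @param K number of brightness regions.
#' @param beta linear gain; \code{beta = 1} is the identity,
#'   \code{beta > 1} increases contrast around each region mean.
#' @param seed clustering seed (see [kmeans_segment_brightness()]).
#' @return enhanced RGB image array.
#' @export
kmmrc_enhance <- function(img, K = 5L, beta = 1.5, seed = 42L) {
  .assert_fundus(img)
  stopifnot(beta > 0)
  planes <- img2hsv(img)
  part <- kmeans_segment_brightness(planes$V, K, seed)
  M <- matrix(part$region_means[part$labels], nrow(planes$V), ncol(planes$V))
  planes$V <- .clip01(M + beta * (planes$V - M))
  hsv2img(planes)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise histogram equalization with a clip limit, used after KMMRC to
#' smooth false edges introduced by the per-region stretch. Thin wrapper
#' over \code{EBImage::clahe}; \code{clip} is expressed as a fraction of
#' the tile histogram mass and mapped onto EBImage's limit scale.
#'
#' @param gray grayscale matrix in \eqn{[0, 1]}.
#' @param clip clip limit in \eqn{(0, 1]}; 0 returns the input unchanged.
#' @param tiles tile grid \code{c(rows, cols)}; reduced automatically on
#'   images too small for the requested grid.
#' @param bins histogram bin count.
#' @return equalized grayscale matrix in \eqn{[0, 1]}.
#' @export
clahe_enhance <- function(gray, clip = 0.01, tiles = c(8L, 8L), bins = 256L) {
  .assert_gray(gray)
  if (clip <= 0) return(gray)
  if (diff(range(gray)) == 0) return(gray)  # nothing to equalize
  tiles <- pmax(pmin(as.integer(tiles), dim(gray) %/% 2L), 2L)
  # EBImage requires each dimension to be a multiple of the tile grid;
  # pad by edge reflection and crop back afterwards
  nr <- nrow(gray); nc <- ncol(gray)
  pr <- (tiles[1L] - nr %% tiles[1L]) %% tiles[1L]
  pc <- (tiles[2L] - nc %% tiles[2L]) %% tiles[2L]
  padded <- gray[c(seq_len(nr), nr:(nr - pr + 1L))[seq_len(nr + pr)],
                 c(seq_len(nc), nc:(nc - pc + 1L))[seq_len(nc + pc)],
                 drop = FALSE]
  out <- EBImage::clahe(t(padded), nx = tiles[2L], ny = tiles[1L],
                        bins = bins, limit = max(clip * bins, 1))
  .clip01(t(out)[seq_len(nr), seq_len(nc), drop = FALSE])
}

#' Average (box) filter
#'
#' Replaces each pixel by the mean of the surrounding
#' \code{window} x \code{window} neighborhood, with reflected borders.
#'
#' @param gray grayscale matrix.
#' @param window odd window side length; 1 is the identity.
#' @return smoothed grayscale matrix.
#' @export
average_filter <- function(gray, window = 5L) {
  .assert_gray(gray)
  if (window < 1 || window %% 2 != 1)
    stop("average filter window must be an odd positive integer, got ",
         window)
  .box_mean(gray, as.integer(window))
}

#' Full preprocessing stage
#'
#' Composition of the four preprocessing steps, in order: KMMRC local
#' contrast enhancement on the color image, green-channel extraction,
#' CLAHE global contrast enhancement, average-filter noise smoothing.
#' The result is the grayscale input of candidate generation.
#'
#' @param img RGB image array in \eqn{[0, 1]}.
#' @param params [hemseg_params()] object.
#' @param keep_stages if \code{TRUE}, the four intermediate results are
#'   returned in an attribute \code{"stages"}.
#' @param dump_dir optional directory; when given, the four stage outputs
#'   are written as \code{01_kmmrc.png} ... \code{04_avgfilter.png}.
#' @return preprocessed grayscale matrix.
#' @export
preprocess_fundus <- function(img, params = hemseg_params(),
                              keep_stages = FALSE, dump_dir = NULL) {
  .assert_fundus(img)
  s1 <- kmmrc_enhance(img, params$K, params$beta, params$kmeans_seed)
  s2 <- extract_green_gray(s1)
  s3 <- clahe_enhance(s2, params$clahe_clip, params$clahe_tiles,
                      params$clahe_bins)
  s4 <- average_filter(s3, params$filter_window)
  if (!is.null(dump_dir)) {
    dir.create(dump_dir, showWarnings = FALSE, recursive = TRUE)
    write_image(s1, file.path(dump_dir, "01_kmmrc.png"))
    write_mask_gray <- function(g, p) EBImage::writeImage(EBImage::Image(t(g)), p)
    write_mask_gray(s2, file.path(dump_dir, "02_green.png"))
    write_mask_gray(s3, file.path(dump_dir, "03_clahe.png"))
    write_mask_gray(s4, file.path(dump_dir, "04_avgfilter.png"))
  }
  if (keep_stages)
    attr(s4, "stages") <- list(kmmrc = s1, green = s2, clahe = s3,
                               avgfilter = s4)
  s4
}
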