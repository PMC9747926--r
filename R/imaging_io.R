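# Image and mask input/output plus color-space conversion.
#
# Internal conventions: an RGB fundus image is a numeric array of
# dimension c(rows, cols, 3) with values in [0, 1]; a grayscale plane is a
# numeric matrix in [0, 1]; a mask is a logical matrix. Row 1 is the top
# of the image. 8-bit quantization happens only at file boundaries.

.assert_fundus <- function(img) {
  if (!(is.array(img) && length(dim(img)) == 3L && dim(img)[3L] == 3L))
    stop("expected an RGB image array of dimension (rows, cols, 3)")
  if (anyNA(img) || min(img) < 0 || max(img) > 1)
    stop("image channel values must lie in [0, 1]")
  invisible(img)
}

.assert_gray <- function(gray) {
  if (!is.matrix(gray) || !is.numeric(gray))
    stop("expected a numeric matrix grayscale plane")
  if (anyNA(gray) || min(gray) < 0 || max(gray) > 1)
    stop("grayscale values must lie in [0, 1]")
  invisible(gray)
}

#' Read an RGB fundus image
#'
#' Reads a PNG or JPEG file into a numeric array of dimension
#' \code{(rows, cols, 3)} with channel values rescaled to \eqn{[0, 1]}.
#'
#' @param path path to a PNG or JPEG file.
#' @return numeric array \code{(rows, cols, 3)} in \eqn{[0, 1]}.
#' @seealso [write_image()], [read_mask()]
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image, no such file: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("unreadable image file: ", path,
                                           " (", conditionMessage(e), ")"))
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) < 3L)
    stop("single-channel input, expected an RGB image: ", path)
  if (dim(dat)[3L] > 3L) dat <- dat[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(dat)[3L] != 3L)
    stop("expected 3 color channels, got ", dim(dat)[3L], ": ", path)
  .clip01(aperm(dat, c(2L, 1L, 3L)))
}

#' Write an RGB fundus image
#'
#' @param img numeric array \code{(rows, cols, 3)} in \eqn{[0, 1]}.
#' @param path output path; format chosen from the extension (.png, .jpg).
#' @param quality JPEG quality (ignored for PNG).
#' @return the path, invisibly.
#' @export
write_image <- function(img, path, quality = 100) {
  .assert_fundus(img)
  out <- EBImage::Image(aperm(img, c(2L, 1L, 3L)), colormode = "Color")
  EBImage::writeImage(out, path, quality = quality)
  invisible(path)
}

#' Read a binary mask from a PNG file
#'
#' Nonzero pixels are treated as positive. Multi-channel mask files are
#' reduced by "any channel nonzero".
#'
#' @param path path to a PNG file.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("cannot read mask, no such file: ", path)
  dat <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(dat)) == 3L) dat <- apply(dat, c(1L, 2L), max)
  t(dat) > 0
}

#' Write a binary mask as a single-channel PNG
#'
#' @param mask logical matrix.
#' @param path output path (.png).
#' @return the path, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  EBImage::writeImage(EBImage::Image(t(mask) * 1), path)
  invisible(path)
}

#' Extract the green channel as the working grayscale plane
#'
#' The green channel offers the best contrast for dark red lesions such as
#' hemorrhages, so it is used as the grayscale input of the segmentation
#' stages.
#'
#' @param img RGB image array.
#' @return numeric matrix equal to the green plane, bit for bit.
#' @export
extract_green_gray <- function(img) {
  .assert_fundus(img)
  matrix(img[, , 2L], dim(img)[1L], dim(img)[2L])
}

#' RGB to HSV plane decomposition
#'
#' Standard hexcone conversion. All three planes are on the \eqn{[0, 1]}
#' scale; hue is stored in turns (fraction of a full circle), not degrees,
#' so the three planes share one scale for feature extraction.
#'
#' @param img RGB image array \code{(rows, cols, 3)} in \eqn{[0, 1]}.
#' @return list with matrices \code{H}, \code{S}, \code{V}.
#' @seealso [hsv2img()]
#' @export
img2hsv <- function(img) {
  .assert_fundus(img)
  dm <- dim(img)[1:2]
  m <- rgb2hsv(as.vector(img[, , 1L]), as.vector(img[, , 2L]),
               as.vector(img[, , 3L]), maxColorValue = 1)
  list(H = matrix(m[1L, ], dm[1L], dm[2L]) %% 1,
       S = matrix(m[2L, ], dm[1L], dm[2L]),
       V = matrix(m[3L, ], dm[1L], dm[2L]))
}

#' HSV planes to RGB image
#'
#' Inverse hexcone conversion; \code{hsv2img(img2hsv(x))} reproduces
#' \code{x} to floating-point accuracy.
#'
#' @param planes list with matrices \code{H} (turns, in \eqn{[0,1)}),
#'   \code{S} and \code{V} (in \eqn{[0,1]}), all of one shape.
#' @return RGB image array \code{(rows, cols, 3)}.
#' @export
hsv2img <- function(planes) {
  H <- planes$H; S <- planes$S; V <- planes$V
  stopifnot(is.matrix(H), all(dim(H) == dim(S)), all(dim(H) == dim(V)))
  h6 <- (H %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- V * (1 - S)
  q <- V * (1 - S * f)
  t <- V * (1 - S * (1 - f))
  r <- V; g <- V; b <- V
  sel <- i == 0; r[sel] <- V[sel]; g[sel] <- t[sel]; b[sel] <- p[sel]
  sel <- i == 1; r[sel] <- q[sel]; g[sel] <- V[sel]; b[sel] <- p[sel]
  sel <- i == 2; r[sel] <- p[sel]; g[sel] <- V[sel]; b[sel] <- t[sel]
  sel <- i == 3; r[sel] <- p[sel]; g[sel] <- q[sel]; b[sel] <- V[sel]
  sel <- i == 4; r[sel] <- t[sel]; g[sel] <- p[sel]; b[sel] <- V[sel]
  sel <- i == 5; r[sel] <- V[sel]; g[sel] <- p[sel]; b[sel] <- q[sel]
  out <- array(0, c(dim(H), 3L))
  out[, , 1L] <- r; out[, , 2L] <- g; out[, , 3L] <- b
  .clip01(out)
}
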