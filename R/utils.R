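# Internal numeric helpers shared across pipeline stages.

`%||%` <- function(a, b) if (is.null(a)) b else a

.clip01 <- function(x) pmin(pmax(x, 0), 1)

# Run expr with a fixed RNG seed, restoring the caller's RNG state after.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Symmetric (edge-inclusive) reflection padding by r pixels on every side.
.reflect_pad <- function(m, r) {
  if (r == 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  if (r > nr || r > nc)
    stop("reflection pad of ", r, " pixels exceeds image extent (",
         nr, "x", nc, ")")
  ridx <- c(r:1, seq_len(nr), nr:(nr - r + 1L))
  cidx <- c(r:1, seq_len(nc), nc:(nc - r + 1L))
  m[ridx, cidx, drop = FALSE]
}

# Sum of each side x side window centered on every pixel, borders reflected.
# Integral-image formulation: O(1) per pixel.
.box_sum <- function(m, side) {
  stopifnot(side >= 1L, side %% 2L == 1L)
  if (side == 1L) return(m)
  r <- (side - 1L) %/% 2L
  p <- .reflect_pad(m, r)
  cs <- apply(p, 2, cumsum)
  cs <- t(apply(cs, 1, cumsum))
  S <- matrix(0, nrow(p) + 1L, ncol(p) + 1L)
  S[-1L, -1L] <- cs
  i <- seq_len(nrow(m)); j <- seq_len(ncol(m))
  S[i + side, j + side, drop = FALSE] - S[i, j + side, drop = FALSE] -
    S[i + side, j, drop = FALSE] + S[i, j, drop = FALSE]
}

.box_mean <- function(m, side) .box_sum(m, side) / side^2

# 8-connected component labeling of a logical matrix.
# Two-pass union-find over the four backward neighbor offsets.
.label8 <- function(mask) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  fg <- which(mask)
  k <- length(fg)
  if (k == 0L) return(lab)
  id <- matrix(0L, nr, nc)
  id[fg] <- seq_len(k)
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  row <- ((fg - 1L) %% nr) + 1L
  col <- ((fg - 1L) %/% nr) + 1L
  offsets <- list(c(-1L, -1L), c(0L, -1L), c(1L, -1L), c(-1L, 0L))
  for (off in offsets) {
    nrw <- row + off[1L]; ncl <- col + off[2L]
    ok <- nrw >= 1L & nrw <= nr & ncl >= 1L & ncl <= nc
    if (!any(ok)) next
    nidx <- (ncl[ok] - 1L) * nr + nrw[ok]
    hit <- mask[nidx]
    a <- id[fg[ok][hit]]
    b <- id[nidx[hit]]
    for (e in seq_along(a)) {
      ra <- find(a[e]); rb <- find(b[e])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  relabel <- match(roots, sort(unique(roots)))
  lab[fg] <- relabel
  lab
}

# Moment-fitted ellipse axis lengths of a pixel set, with the 1/12
# single-pixel variance correction so an isolated pixel has unit axes.
# Axis length convention: 4 * sqrt(eigenvalue of the pixel covariance).
.ellipse_axes <- function(rows, cols) {
  n <- length(rows)
  mr <- mean(rows); mc <- mean(cols)
  dr <- rows - mr; dc <- cols - mc
  vrr <- sum(dr * dr) / n + 1 / 12
  vcc <- sum(dc * dc) / n + 1 / 12
  vrc <- sum(dr * dc) / n
  tr <- vrr + vcc
  det <- sqrt(max((vrr - vcc)^2 / 4 + vrc^2, 0))
  l1 <- tr / 2 + det
  l2 <- max(tr / 2 - det, 0)
  c(major = 4 * sqrt(l1), minor = 4 * sqrt(l2),
    centroid_row = mr, centroid_col = mc)
}

# Coerce a point set (logical mask or n x 2 [row, col] matrix) to linear
# indices into a grid of dimension dm = c(nrow, ncol).
.as_index <- function(pts, dm) {
  if (is.logical(pts) && is.matrix(pts)) {
    if (!is.null(dm) && !all(dim(pts) == dm))
      stop("point-set mask shape does not match image shape")
    return(which(pts))
  }
  if (is.matrix(pts) && ncol(pts) == 2L) {
    if (is.null(dm)) stop("image shape required for coordinate point sets")
    if (nrow(pts) == 0L) return(integer(0))
    if (any(pts[, 1L] < 1L | pts[, 1L] > dm[1L] |
            pts[, 2L] < 1L | pts[, 2L] > dm[2L]))
      stop("point coordinates outside image bounds")
    return(unique((pts[, 2L] - 1L) * dm[1L] + pts[, 1L]))
  }
  stop("point set must be a logical mask or a two-column [row, col] matrix")
}

#' Convert a point set to a binary mask
#'
#' @param pts logical mask or two-column integer matrix of (row, col)
#'   coordinates.
#' @param dim image dimensions \code{c(rows, cols)}.
#' @return logical matrix of the given dimension.
#' @export
points_to_mask <- function(pts, dim) {
  m <- matrix(FALSE, dim[1L], dim[2L])
  m[.as_index(pts, dim)] <- TRUE
  m
}

#' Convert a binary mask to (row, col) coordinates
#'
#' @param mask logical matrix.
#' @return integer matrix with columns \code{row}, \code{col}.
#' @export
mask_to_points <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  w <- which(mask, arr.ind = TRUE)
  colnames(w) <- c("row", "col")
  w
}
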