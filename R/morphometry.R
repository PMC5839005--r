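# Per-cell shape morphometry.
#
# A "footprint" is either a logical matrix (raster mask) or a 2-column
# matrix of 0-based (x, y) pixel-center coordinates.

footprint_xy <- function(footprint) {
  if (is.matrix(footprint) && !is.logical(footprint) && ncol(footprint) == 2L)
    return(footprint)
  w <- which(footprint, arr.ind = TRUE)
  cbind(x = w[, 2] - 1, y = w[, 1] - 1)
}

#' Oriented bounding box of a segmented object
#'
#' The box axes are the eigenvectors of the (population) covariance matrix
#' of the object's pixel-center coordinates; the box spans the min/max
#' extent of the pixel centers along those axes, plus one pixel so that a
#' one-pixel-wide line has nonzero width.
#'
#' @param footprint logical mask or 2-column (x, y) pixel matrix.
#' @param um_per_px microns per pixel.
#' @return list with \code{length_um}, \code{width_um} (length >= width)
#'   and \code{orientation_rad} (major-axis angle, y-down frame).
#' @export
oriented_bounding_box <- function(footprint, um_per_px) {
  xy <- footprint_xy(footprint)
  n <- nrow(xy)
  if (n < 3L) stop("degenerate footprint: need >= 3 pixels")
  ctr <- colMeans(xy)
  Z <- sweep(xy, 2L, ctr)
  C <- crossprod(Z) / n
  e <- eigen(C, symmetric = TRUE)
  v1 <- e$vectors[, 1]; v2 <- e$vectors[, 2]
  p1 <- Z %*% v1; p2 <- Z %*% v2
  ext1 <- diff(range(p1)) + 1
  ext2 <- diff(range(p2)) + 1
  len <- max(ext1, ext2); wid <- min(ext1, ext2)
  vmaj <- if (ext1 >= ext2) v1 else v2
  list(length_um = len * um_per_px, width_um = wid * um_per_px,
       orientation_rad = atan2(vmaj[2], vmaj[1]) %% pi)
}

#' Ellipticity of a segmented object
#'
#' Minor/major axis-length ratio of the moment-equivalent ellipse
#' (\code{sqrt(lambda2/lambda1)} of the coordinate covariance); 1 for a
#' circle, small for line-like shapes.
#'
#' @inheritParams oriented_bounding_box
#' @return numeric in \code{[0, 1]}.
#' @export
ellipticity <- function(footprint) {
  xy <- footprint_xy(footprint)
  if (nrow(xy) < 3L) stop("degenerate footprint: need >= 3 pixels")
  Z <- sweep(xy, 2L, colMeans(xy))
  lam <- eigen(crossprod(Z) / nrow(xy), symmetric = TRUE, only.values = TRUE)$values
  if (lam[1] <= 0) return(1)
  sqrt(max(lam[2], 0) / lam[1])
}

# contour perimeter of a binary mask (8-connected chain length)
contour_perimeter <- function(mask) {
  oc <- EBImage::ocontour(as_ebi(mask * 1))
  if (!length(oc)) return(0)
  sum(vapply(oc, function(ch) {
    if (nrow(ch) < 2L) return(0)
    d <- sqrt(rowSums((ch - ch[c(2:nrow(ch), 1L), , drop = FALSE])^2))
    sum(d)
  }, 0))
}

#' Compactness (isoperimetric quotient) of a segmented object
#'
#' \code{4 * pi * area / perimeter^2} with the perimeter measured as the
#' 8-connected contour chain length; about 1 for a disc, lower for ragged
#' or elongated shapes.  Footprints too small to carry a contour (< 5
#' pixels) return 1 by convention.
#'
#' @param footprint logical mask (raster) of the object.
#' @return numeric in \code{(0, 1]}.
#' @export
compactness <- function(footprint) {
  if (!is.logical(footprint))
    stop("compactness requires a logical raster footprint")
  a <- sum(footprint)
  if (a == 0L) stop("empty footprint")
  if (a < 5L) return(1)
  p <- contour_perimeter(footprint)
  if (p <= 0) return(1)
  min(1, 4 * pi * a / p^2)
}

#' Completeness of membrane labeling
#'
#' The object's boundary pixels are binned by their angle around the
#' centroid (equal-angle bins); the returned value is the fraction of
#' occupied bins whose mean CD8 OD exceeds the positivity threshold.
#' Footprints with fewer than 8 boundary pixels fall back to the fraction
#' of all footprint pixels above threshold.
#'
#' @param footprint logical raster mask (same frame as \code{cd8_field}).
#' @param cd8_field CD8 chromogen OD matrix.
#' @param threshold positivity threshold (scalar or matrix of the same
#'   frame).
#' @param n_bins number of angular bins (default 16).
#' @return numeric in \code{[0, 1]}.
#' @export
membrane_completeness <- function(footprint, cd8_field, threshold,
                                  n_bins = 16L) {
  idx <- which(footprint)
  if (!length(idx)) stop("empty footprint")
  thr_at <- function(i) if (is.matrix(threshold)) threshold[i] else threshold
  er <- from_ebi(EBImage::erode(as_ebi(footprint * 1),
                                EBImage::makeBrush(3, "box"))) > 0.5
  boundary <- footprint & !er
  bidx <- which(boundary)
  if (length(bidx) < 8L) {
    return(mean(cd8_field[idx] > thr_at(idx)))
  }
  nr <- nrow(footprint)
  by <- (bidx - 1L) %% nr          # 0-based row (y)
  bx <- (bidx - 1L) %/% nr         # 0-based col (x)
  cy <- mean((idx - 1L) %% nr); cx <- mean((idx - 1L) %/% nr)
  ang <- atan2(by - cy, bx - cx) %% (2 * pi)
  bin <- pmin(floor(ang / (2 * pi) * n_bins) + 1L, n_bins)
  pos <- cd8_field[bidx] > thr_at(bidx)
  binpos <- tapply(pos, bin, mean)
  mean(binpos > 0.5)
}

#' Elongate-cell criteria
#'
#' A CD8+ cell qualifies as elongate when it is isolated from other CD8+
#' cells and its oriented bounding box has width strictly below
#' \code{max_width_um} and length-to-width ratio strictly above
#' \code{min_length_width_ratio}.
#'
#' @param max_width_um maximum OBB width (default 10).
#' @param min_length_width_ratio minimum OBB length/width ratio
#'   (default 2.3).
#' @param isolation_distance_um minimum boundary-to-boundary distance to the
#'   nearest other CD8+ cell (default 10, about one mean lymphocyte
#'   diameter; the criterion source states isolation without a number).
#' @return object of class \code{elongate_criteria}.
#' @export
elongate_criteria <- function(max_width_um = 10, min_length_width_ratio = 2.3,
                              isolation_distance_um = 10) {
  if (max_width_um <= 0 || min_length_width_ratio <= 0 ||
      isolation_distance_um <= 0)
    stop("all elongate criteria must be positive")
  structure(list(max_width_um = max_width_um,
                 min_length_width_ratio = min_length_width_ratio,
                 isolation_distance_um = isolation_distance_um),
            class = "elongate_criteria")
}

#' Classify elongate CD8+ cells
#'
#' Applies the elongate criteria to a cell table.  Isolation is evaluated
#' as nearest-neighbour centroid distance minus both cells' equivalent
#' radii (\code{sqrt(area/pi)}), an O(n log n)-friendly surrogate for exact
#' boundary distance.
#'
#' @param cells data.frame with columns \code{x_um}, \code{y_um},
#'   \code{area_um2}, \code{obb_length_um}, \code{obb_width_um} and
#'   logical \code{cd8_positive}.
#' @param criteria an [elongate_criteria()].
#' @return \code{cells} with a logical \code{elongate} column (always
#'   \code{FALSE} for CD8- rows).
#' @export
classify_elongate <- function(cells, criteria = elongate_criteria()) {
  n <- nrow(cells)
  cells$elongate <- logical(n)
  pos <- which(cells$cd8_positive)
  if (length(pos) == 0L) return(cells)
  shape_ok <- cells$obb_width_um[pos] < criteria$max_width_um &
    cells$obb_length_um[pos] / cells$obb_width_um[pos] >
      criteria$min_length_width_ratio
  iso <- rep(TRUE, length(pos))
  if (length(pos) > 1L) {
    xy <- cbind(cells$x_um[pos], cells$y_um[pos])
    rad <- sqrt(pmax(cells$area_um2[pos], 0) / pi)
    D <- as.matrix(dist(xy))
    B <- D - outer(rad, rad, "+")
    diag(B) <- Inf
    iso <- apply(B, 1L, min) > criteria$isolation_distance_um
  }
  cells$elongate[pos] <- shape_ok & iso
  cells
}

#' Fraction of elongate CD8+ cells
#'
#' @param cells cell table with \code{cd8_positive}, \code{elongate} and
#'   (optionally) \code{region} columns.
#' @param region optional region label to restrict to (e.g. \code{"TC"}).
#' @return numeric in \code{[0, 1]}, or \code{NA} if the region holds no
#'   CD8+ cell.
#' @export
elongate_fraction <- function(cells, region = NULL) {
  if (!is.null(region) && "region" %in% names(cells))
    cells <- cells[cells$region %in% region, , drop = FALSE]
  npos <- sum(cells$cd8_positive)
  if (npos == 0L) return(NA_real_)
  sum(cells$elongate & cells$cd8_positive) / npos
}
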