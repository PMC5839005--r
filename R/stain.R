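#' Stain color profiles for brightfield IHC
#'
#' A stain profile holds one unit-norm optical-density (OD) color vector per
#' chromogen/counterstain, following the Beer-Lambert model in which stain
#' contributions add linearly in OD space.  Two built-in modes cover the
#' assays handled by this package: \code{"mono_dab"} (hematoxylin
#' counterstain + DAB brown CD8 chromogen) and \code{"dual_purple_dab"}
#' (hematoxylin + purple CD8 chromogen + DAB brown PD-L1).  The hematoxylin
#' and DAB vectors are the widely used Ruifrok-Johnston color-deconvolution
#' values; the purple vector is the profile used by the synthetic renderer.
#' Real-slide work with other chromogens should supply measured vectors.
#'
#' @param mode \code{"mono_dab"} or \code{"dual_purple_dab"}, or a named list
#'   of numeric length-3 OD vectors (named by stain) for a custom profile.
#' @return An object of class \code{stain_profile}: list with \code{names},
#'   \code{vectors} (3 x n matrix, columns unit-norm) and \code{mode}.
#' @examples
#' stain_profile("mono_dab")
#' @export
stain_profile <- function(mode = c("mono_dab", "dual_purple_dab")) {
  vecs <- list(
    hematoxylin = c(0.650, 0.704, 0.286),
    dab         = c(0.268, 0.570, 0.776),
    purple      = c(0.380, 0.850, 0.365)
  )
  if (is.list(mode)) {
    custom <- mode
    if (is.null(names(custom)) || any(!nzchar(names(custom))))
      stop("custom stain profile must be a named list of OD vectors")
    V <- vapply(custom, function(v) {
      v <- as.numeric(v)
      if (length(v) != 3L || any(!is.finite(v)) || sum(v^2) == 0)
        stop("each stain vector must be a finite numeric triple")
      v / sqrt(sum(v^2))
    }, numeric(3))
    mode_lab <- "custom"
  } else {
    mode_lab <- match.arg(mode)
    sel <- if (mode_lab == "mono_dab") c("hematoxylin", "dab")
           else c("hematoxylin", "purple", "dab")
    V <- vapply(vecs[sel], function(v) v / sqrt(sum(v^2)), numeric(3))
  }
  structure(list(names = colnames(V), vectors = V, mode = mode_lab),
            class = "stain_profile")
}

#' @export
print.stain_profile <- function(x, ...) {
  cat("Stain profile (", x$mode, "): ", paste(x$names, collapse = ", "),
      "\n", sep = "")
  print(round(x$vectors, 3))
  invisible(x)
}

#' Convert an 8-bit RGB raster to optical density
#'
#' Per channel, \code{OD = -log10((I + eps) / 255)} so a white pixel maps to
#' (near) zero OD and OD decreases monotonically with transmitted intensity.
#'
#' @param rgb numeric array \code{[rows, cols, 3]} with values in 0..255.
#' @param eps small positive offset guarding \code{log(0)} (default 0.5,
#'   half an intensity level).
#' @return array of the same shape holding per-channel OD (>= 0).
#' @seealso [od_to_rgb()], [unmix_stains()]
#' @export
rgb_to_od <- function(rgb, eps = 0.5) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop("'rgb' must be a [rows, cols, 3] array")
  od <- -log10((rgb + eps) / 255)
  od[od < 0] <- 0
  od
}

#' Render per-stain OD fields back to an RGB raster
#'
#' Inverse of the deconvolution model: channel intensity
#' \code{I_c = 255 * 10^(-sum_s A_s V[c, s])}.  Used by the synthetic slide
#' renderer and by round-trip tests.
#'
#' @param fields list (or 3-d array) of per-stain OD matrices, in profile
#'   stain order.
#' @param profile a [stain_profile()].
#' @param bit8 quantize to integers 0..255 (default TRUE); set FALSE for an
#'   exact (continuous) rendering.
#' @return numeric array \code{[rows, cols, 3]}.
#' @export
od_to_rgb <- function(fields, profile, bit8 = TRUE) {
  if (is.list(fields)) fields <- simplify2array(fields)
  d <- dim(fields)
  ns <- ncol(profile$vectors)
  if (length(d) == 2L) fields <- array(fields, c(d, 1L))
  if (dim(fields)[3] != ns)
    stop("number of OD fields must match the stain profile")
  nr <- dim(fields)[1]; nc <- dim(fields)[2]
  A <- matrix(fields, nr * nc, ns)
  odrgb <- A %*% t(profile$vectors)
  I <- 255 * 10^(-odrgb)
  if (bit8) I <- round(pmin(pmax(I, 0), 255))
  array(I, c(nr, nc, 3L))
}

#' Unmix an OD raster into per-stain fields
#'
#' Least-squares projection of each pixel's 3-component OD vector onto the
#' profile's stain vectors (color deconvolution); negative loadings are
#' clipped to zero.  On noise-free input rendered from the same profile the
#' planted fields are recovered exactly up to quantization.
#'
#' @param od OD array \code{[rows, cols, 3]} from [rgb_to_od()].
#' @param profile a [stain_profile()] with at most 3 stains.
#' @return An object of class \code{stain_fields}: named list of per-stain
#'   OD matrices plus \code{tissue_mask = NULL} (filled by callers).
#' @export
unmix_stains <- function(od, profile) {
  V <- profile$vectors
  if (ncol(V) > 3L) stop("at most 3 stains supported")
  if (qr(V)$rank < ncol(V))
    stop("stain matrix is rank deficient (collinear stain vectors)")
  d <- dim(od)
  X <- matrix(od, d[1] * d[2], 3L)
  # pseudo-inverse projection: A = (V'V)^-1 V' od
  P <- solve(crossprod(V), t(V))
  A <- X %*% t(P)
  A[A < 0] <- 0
  out <- lapply(seq_len(ncol(V)), function(j) matrix(A[, j], d[1], d[2]))
  names(out) <- profile$names
  structure(list(fields = out, profile = profile), class = "stain_fields")
}

#' Detect tissue (vs. glass background)
#'
#' Pixels whose total OD (sum over RGB channels) exceeds a small fixed floor
#' are tissue; the mask is then morphologically closed and opened to remove
#' pinholes and isolated specks.
#'
#' @param od OD array from [rgb_to_od()].
#' @param floor total-OD floor separating glass from tissue (default 0.08).
#' @param brush_px diameter of the closing/opening structuring element.
#' @return logical matrix tissue mask.
#' @export
detect_tissue <- function(od, floor = 0.08, brush_px = 7L) {
  tot <- od[, , 1] + od[, , 2] + od[, , 3]
  m <- tot > floor
  if (!any(m)) return(m)
  kern <- EBImage::makeBrush(brush_px, shape = "disc")
  e <- as_ebi(m * 1)
  e <- EBImage::closing(e, kern)
  e <- EBImage::opening(e, kern)
  from_ebi(e) > 0.5
}

#' Adaptive positive-stain threshold
#'
#' The positivity threshold for a stain field is the pointwise maximum of a
#' global floor and a local background statistic, \code{local mean + k *
#' local sd}, estimated in a sliding square window restricted to tissue.
#' The statistics are computed in two passes: a provisional threshold from
#' all tissue pixels, then final statistics from the pixels below it, so
#' that strongly stained membranes do not inflate their own threshold even
#' in densely infiltrated regions.  This keeps positivity decisions stable
#' under slowly varying illumination and background staining.
#'
#' @param field per-stain OD matrix (from [unmix_stains()]).
#' @param tissue_mask logical matrix; must contain at least one pixel.
#' @param floor global minimum threshold in OD units (default 0.15).
#' @param k multiplier on the local background SD (default 3).
#' @param window_px sliding-window width (default 256 px; much larger than a
#'   lymphocyte, much smaller than the illumination scale).
#' @return list with \code{mask} (logical positive-pixel matrix) and
#'   \code{threshold} (the per-pixel threshold matrix actually applied).
#' @export
adaptive_threshold <- function(field, tissue_mask, floor = 0.15, k = 3,
                               window_px = 256L) {
  if (!any(tissue_mask)) stop("empty tissue mask")
  half <- as.integer(window_px) %/% 2L
  # background/foreground split: global Otsu on the tissue histogram keeps
  # stained membranes out of the background sample even when they are the
  # locally dominant class
  fv <- field[tissue_mask]
  cut <- max(otsu_threshold(fv), floor)
  bg <- tissue_mask & (field < cut)
  if (!any(bg)) bg <- tissue_mask
  w <- bg * 1
  f <- field * w
  nw <- box_mean(w, half)
  cov_ok <- nw > 0.02          # windows nearly devoid of background pixels
  nw[!cov_ok] <- NA            # fall back to global background statistics
  mu <- box_mean(f, half) / nw
  mu2 <- box_mean(f * f, half) / nw
  s <- sqrt(pmax(mu2 - mu^2, 0))
  bv <- field[bg]
  mu_g <- mean(bv); s_g <- sd(bv)
  if (!is.finite(s_g)) s_g <- 0
  thr <- pmax(mu + k * s, floor)
  thr[is.na(thr)] <- max(mu_g + k * s_g, floor)
  mask <- (field > thr) & tissue_mask
  list(mask = mask, threshold = thr)
}

# Otsu's between-class-variance threshold on a numeric sample
otsu_threshold <- function(x, n_breaks = 256L) {
  rng <- range(x)
  if (diff(rng) <= 0) return(rng[1])
  h <- tabulate(pmin(as.integer((x - rng[1]) / diff(rng) * n_breaks) + 1L,
                     n_breaks), nbins = n_breaks)
  w <- h / sum(h)
  mids <- rng[1] + (seq_len(n_breaks) - 0.5) / n_breaks * diff(rng)
  w1 <- cumsum(w)
  m1 <- cumsum(w * mids)
  mT <- m1[n_breaks]
  bcv <- (mT * w1 - m1)^2 / (w1 * (1 - w1))
  bcv[!is.finite(bcv)] <- 0
  mids[which.max(bcv)]
}
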