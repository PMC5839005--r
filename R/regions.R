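# Region geometry: tumor / tumor-center (TC) / invasive-margin (IM) /
# exclusion regions in slide pixel coordinates.
#
# Polygons are matrices cbind(x, y), 0-based pixel coordinates (y-down),
# vertices at pixel centers.  Region membership and areas are evaluated on
# rasterized masks: a pixel belongs to a polygon when its center is inside
# (even-odd rule, boundary counts as inside).  The IM/TC band construction
# uses Euclidean distance-transform buffering of the rasterized tumor, an
# algorithmic surrogate for the pathologist's free-hand ~250 um band.

#' Construct a region set
#'
#' @param tumor,tc,im,exclusions lists of polygon matrices (\code{cbind(x,
#'   y)}, 0-based px).  \code{tc}/\code{im} are normally produced by
#'   [build_regions()], not supplied directly.
#' @param frame integer pair (rows, cols) of the slide raster.
#' @param um_per_px microns per pixel.
#' @param masks optional named list of precomputed logical masks (used by
#'   [build_regions()], which works in mask space).
#' @return object of class \code{region_set}.
#' @export
region_set <- function(tumor = list(), tc = list(), im = list(),
                       exclusions = list(), frame, um_per_px,
                       masks = list()) {
  stopifnot_scalar(um_per_px, "um_per_px", positive = TRUE)
  frame <- as.integer(rep(frame, length.out = 2L))
  polys <- list(tumor = tumor, tc = tc, im = im, exclusions = exclusions)
  polys <- lapply(polys, function(ps) lapply(ps, as_polygon))
  structure(list(polys = polys, frame = frame, um_per_px = um_per_px,
                 cache = as.environment(masks)), class = "region_set")
}

as_polygon <- function(p) {
  p <- as.matrix(p)
  storage.mode(p) <- "double"   # integer coords overflow in cross products
  if (ncol(p) != 2L || nrow(p) < 3L)
    stop("polygon must be a matrix with columns x, y and >= 3 vertices")
  colnames(p) <- c("x", "y")
  p
}

#' @export
print.region_set <- function(x, ...) {
  n <- vapply(x$polys, length, 0L)
  m <- ls(x$cache)
  cat(sprintf("RegionSet %dx%d px at %.3g um/px | polygons: %s | masks: %s\n",
              x$frame[1], x$frame[2], x$um_per_px,
              paste(sprintf("%s=%d", names(n), n), collapse = " "),
              if (length(m)) paste(m, collapse = " ") else "none"))
  invisible(x)
}

# Rasterize a list of polygons onto the region frame (union; even-odd rule,
# boundary pixels inside).
rasterize_polygons <- function(polys, frame) {
  m <- matrix(FALSE, frame[1], frame[2])
  if (!length(polys)) return(m)
  xs <- rep(0:(frame[2] - 1L), each = frame[1])
  ys <- rep(0:(frame[1] - 1L), times = frame[2])
  for (p in polys) {
    # restrict the point grid to the polygon bounding box
    keep <- xs >= min(p[, 1]) - 1 & xs <= max(p[, 1]) + 1 &
            ys >= min(p[, 2]) - 1 & ys <= max(p[, 2]) + 1
    if (!any(keep)) next
    inside <- pracma::inpolygon(xs[keep], ys[keep], p[, 1], p[, 2],
                                boundary = TRUE)
    m[cbind(ys[keep][inside] + 1L, xs[keep][inside] + 1L)] <- TRUE
  }
  m
}

#' Region mask lookup
#'
#' Returns (and caches) the logical raster of a named region.  Regions
#' created by [build_regions()] are mask-backed; polygon-backed regions are
#' rasterized on first use.
#'
#' @param rs a [region_set()].
#' @param name one of \code{"tumor"}, \code{"tc"}, \code{"im"},
#'   \code{"exclusions"}.
#' @return logical matrix.
#' @export
region_mask <- function(rs, name) {
  if (!name %in% names(rs$polys)) stop("unknown region name: ", name)
  if (!is.null(rs$cache[[name]])) return(rs$cache[[name]])
  m <- rasterize_polygons(rs$polys[[name]], rs$frame)
  assign(name, m, envir = rs$cache)
  m
}

# crude self-intersection (bow-tie) check: any two non-adjacent edges cross
polygon_self_intersects <- function(p) {
  storage.mode(p) <- "double"
  n <- nrow(p)
  seg <- cbind(p, p[c(2:n, 1), ])
  crosses <- function(a, b) {
    d <- function(p1, p2, p3)
      (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d1 <- d(a[1:2], a[3:4], b[1:2]); d2 <- d(a[1:2], a[3:4], b[3:4])
    d3 <- d(b[1:2], b[3:4], a[1:2]); d4 <- d(b[1:2], b[3:4], a[3:4])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next
      if (crosses(seg[i, ], seg[j, ])) return(TRUE)
    }
  }
  FALSE
}

#' Read / write pathologist annotations (GeoJSON)
#'
#' Annotations are a GeoJSON FeatureCollection of Polygon features whose
#' \code{role} property is one of \code{"tumor"}, \code{"exclusion"} or
#' \code{"margin_line"}.  Coordinates are slide pixel coordinates (0-based,
#' y-down).  Round-tripping preserves geometry to better than 1e-6 px.
#'
#' @param path file path.
#' @param frame,um_per_px raster frame and calibration to attach to the
#'   returned [region_set()].
#' @return \code{read_annotations}: a [region_set()] (margin-line features
#'   are attached as the \code{"margin_line"} attribute).
#' @export
read_annotations <- function(path, frame, um_per_px) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(g$type) || g$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection")
  tumor <- list(); excl <- list(); margin <- list()
  for (k in seq_along(g$features)) {
    f <- g$features[[k]]
    role <- f$properties$role
    if (is.null(role))
      stop(sprintf("feature %d has no 'role' property", k))
    ring <- f$geometry$coordinates[[1]]
    p <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
    # GeoJSON rings repeat the first vertex; drop the closure
    if (nrow(p) > 1 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    colnames(p) <- c("x", "y")
    if (polygon_self_intersects(p))
      stop(sprintf("feature %d ('%s') is self-intersecting", k, role))
    if (role == "tumor") tumor <- c(tumor, list(p))
    else if (role == "exclusion") excl <- c(excl, list(p))
    else if (role == "margin_line") margin <- c(margin, list(p))
    else stop(sprintf("feature %d has unknown role '%s'", k, role))
  }
  rs <- region_set(tumor = tumor, exclusions = excl, frame = frame,
                   um_per_px = um_per_px)
  attr(rs, "margin_line") <- margin
  rs
}

#' @rdname read_annotations
#' @param rs a [region_set()].
#' @export
write_annotations <- function(rs, path) {
  feat <- function(p, role) list(
    type = "Feature",
    properties = list(role = role),
    geometry = list(type = "Polygon",
                    coordinates = list(lapply(
                      seq_len(nrow(p) + 1L),
                      function(i) {
                        j <- if (i > nrow(p)) 1L else i
                        c(p[j, 1], p[j, 2])
                      }))))
  features <- c(lapply(rs$polys$tumor, feat, role = "tumor"),
                lapply(rs$polys$exclusions, feat, role = "exclusion"),
                lapply(attr(rs, "margin_line") %||% list(), feat,
                       role = "margin_line"))
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Margin configuration
#'
#' @param band_outer_um band width outside the tumor boundary (default 250).
#' @param band_inner_um band width inside the tumor boundary (default 250).
#' @param mode \code{"resection_im_tc"} (IM band + interior TC),
#'   \code{"clinical_tumor_only"} (single tumor annotation extended outward,
#'   no IM) or \code{"no_im"} (TC = tumor as annotated; used e.g. for
#'   lymphoma where an IM is not meaningful).
#' @return object of class \code{margin_config}.
#' @export
margin_config <- function(band_outer_um = 250, band_inner_um = 250,
                          mode = c("resection_im_tc", "clinical_tumor_only",
                                   "no_im")) {
  mode <- match.arg(mode)
  if (band_outer_um < 0 || band_inner_um < 0) stop("band widths must be >= 0")
  structure(list(band_outer_um = band_outer_um, band_inner_um = band_inner_um,
                 mode = mode), class = "margin_config")
}

#' Build TC and IM regions from a tumor annotation
#'
#' In \code{resection_im_tc} mode the invasive margin is the band extending
#' \code{band_outer_um} beyond and \code{band_inner_um} inside the annotated
#' tumor boundary (Euclidean buffering, round joins); the tumor center is
#' the remaining tumor interior.  In \code{clinical_tumor_only} mode the
#' single "tumor" annotation is extended \code{band_outer_um} outward and
#' used whole as TC with no IM.  In \code{no_im} mode TC equals the tumor
#' annotation.  Exclusion polygons are subtracted from both TC and IM.
#'
#' @param rs a [region_set()] carrying tumor (and exclusion) polygons, or a
#'   list of tumor polygons plus \code{frame}/\code{um_per_px} arguments.
#' @param config a [margin_config()].
#' @param frame,um_per_px,exclusions used when \code{rs} is a bare polygon
#'   list.
#' @return a [region_set()] with mask-backed \code{tc} and \code{im}
#'   regions.  If the tumor is too thin to survive the inner erosion the TC
#'   may be empty; a warning (not an error) is emitted.
#' @export
build_regions <- function(rs, config = margin_config(), frame = NULL,
                          um_per_px = NULL, exclusions = list()) {
  if (!inherits(rs, "region_set")) {
    if (is.matrix(rs)) rs <- list(rs)
    rs <- region_set(tumor = rs, exclusions = exclusions, frame = frame,
                     um_per_px = um_per_px)
  }
  stopifnot(inherits(config, "margin_config"))
  upp <- rs$um_per_px
  tumor <- region_mask(rs, "tumor")
  excl <- region_mask(rs, "exclusions")
  outer_px <- config$band_outer_um / upp
  inner_px <- config$band_inner_um / upp

  dilate_mask <- function(m, r_px) {
    if (r_px <= 0 || !any(!m)) return(m)
    dt <- from_ebi(EBImage::distmap(as_ebi(1 - m)))
    m | (dt <= r_px)
  }
  erode_mask <- function(m, r_px) {
    if (r_px <= 0 || !any(m)) return(m)
    dt <- from_ebi(EBImage::distmap(as_ebi(m * 1)))
    m & (dt > r_px)
  }

  if (config$mode == "resection_im_tc") {
    outer_buf <- dilate_mask(tumor, outer_px)
    core <- erode_mask(tumor, inner_px)
    im <- outer_buf & !core
    tc <- core
  } else if (config$mode == "clinical_tumor_only") {
    tc <- dilate_mask(tumor, outer_px)
    im <- matrix(FALSE, rs$frame[1], rs$frame[2])
  } else {
    tc <- tumor
    im <- matrix(FALSE, rs$frame[1], rs$frame[2])
  }
  tc <- tc & !excl
  im <- im & !excl
  if (config$mode == "resection_im_tc" && !any(tc) && any(tumor))
    warning("tumor annotation thinner than twice the inner band: TC is empty")
  region_set(tumor = rs$polys$tumor, exclusions = rs$polys$exclusions,
             frame = rs$frame, um_per_px = upp,
             masks = list(tumor = tumor, exclusions = excl, tc = tc, im = im))
}

#' Physical area of a region
#'
#' Area of (region minus exclusions) in mm2: pixel count times
#' \code{(um_per_px/1000)^2}.
#'
#' @param rs a [region_set()].
#' @param name region name.
#' @return area in mm2 (0 for an empty region).
#' @export
region_area_mm2 <- function(rs, name) {
  m <- region_mask(rs, name)
  if (name != "exclusions") m <- m & !region_mask(rs, "exclusions")
  sum(m) * (rs$um_per_px / 1000)^2
}

#' Assign cells to regions
#'
#' Labels each cell by its centroid's region with priority
#' excluded > IM > TC > outside; pixel membership follows the rasterized
#' masks (boundary pixels count as inside), so a centroid on the TC/IM
#' interface takes the IM label.
#'
#' @param cells data.frame with \code{x_px}, \code{y_px} centroid columns
#'   (0-based), e.g. from [segment_cd8()].
#' @param rs a [region_set()] with built \code{tc}/\code{im} masks.
#' @return \code{cells} with a \code{region} factor column
#'   (\code{excluded}, \code{IM}, \code{TC}, \code{outside}).
#' @export
assign_cells_to_regions <- function(cells, rs) {
  lv <- c("excluded", "IM", "TC", "outside")
  if (!nrow(cells)) {
    cells$region <- factor(character(0), levels = lv)
    return(cells)
  }
  r <- round(cells$y_px) + 1L
  c_ <- round(cells$x_px) + 1L
  inframe <- r >= 1L & r <= rs$frame[1] & c_ >= 1L & c_ <= rs$frame[2]
  idx <- cbind(pmin(pmax(r, 1L), rs$frame[1]), pmin(pmax(c_, 1L), rs$frame[2]))
  excl <- region_mask(rs, "exclusions")[idx] & inframe
  im <- region_mask(rs, "im")[idx] & inframe
  tc <- region_mask(rs, "tc")[idx] & inframe
  lab <- rep("outside", nrow(cells))
  lab[tc] <- "TC"; lab[im] <- "IM"; lab[excl] <- "excluded"
  cells$region <- factor(lab, levels = lv)
  cells
}
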