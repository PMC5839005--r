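#' Slide container
#'
#' Bundles an 8-bit RGB raster with its physical calibration and stain
#' profile identifier.  Rasters are base-R arrays \code{[rows, cols, 3]}
#' with the row axis pointing down; pixel coordinates used elsewhere are
#' 0-based (x, y) = (col - 1, row - 1) at pixel centers.
#'
#' @param rgb numeric array \code{[rows, cols, 3]}, values 0..255.
#' @param um_per_px microns per pixel (> 0).
#' @param id slide identifier string.
#' @param stain_mode \code{"mono_dab"} or \code{"dual_purple_dab"}.
#' @return object of class \code{til_slide}.
#' @export
til_slide <- function(rgb, um_per_px, id = "slide",
                      stain_mode = c("mono_dab", "dual_purple_dab")) {
  stain_mode <- match.arg(stain_mode)
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L || any(dim(rgb)[1:2] == 0))
    stop("'rgb' must be a non-empty [rows, cols, 3] array")
  stopifnot_scalar(um_per_px, "um_per_px", positive = TRUE)
  structure(list(rgb = rgb, um_per_px = um_per_px, id = as.character(id),
                 stain_mode = stain_mode), class = "til_slide")
}

#' @export
print.til_slide <- function(x, ...) {
  d <- dim(x$rgb)
  cat(sprintf("IHC slide '%s': %d x %d px at %.3g um/px (%.2f x %.2f mm), %s\n",
              x$id, d[1], d[2], x$um_per_px,
              d[2] * x$um_per_px / 1000, d[1] * x$um_per_px / 1000,
              x$stain_mode))
  invisible(x)
}

#' @export
summary.til_slide <- function(object, ...) {
  print(object)
  cat("channel means:",
      paste(sprintf("%.1f", apply(object$rgb, 3, mean)), collapse = ", "), "\n")
  invisible(object)
}

#' Read / write a slide raster (TIFF or PNG)
#'
#' @param path image file path; format chosen from the extension.
#' @param um_per_px,id,stain_mode metadata to attach on read (rasters carry
#'   no calibration).
#' @return \code{read_slide}: a [til_slide()].
#' @export
read_slide <- function(path, um_per_px, id = basename(path),
                       stain_mode = "mono_dab") {
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) == 2L) img <- EBImage::toRGB(img)
  arr <- EBImage::imageData(img)
  rgb <- aperm(arr[, , 1:3, drop = FALSE], c(2, 1, 3)) * 255
  til_slide(round(rgb), um_per_px = um_per_px, id = id,
            stain_mode = stain_mode)
}

#' @rdname read_slide
#' @param slide a [til_slide()].
#' @export
write_slide <- function(slide, path) {
  arr <- aperm(slide$rgb, c(2, 1, 3)) / 255
  EBImage::writeImage(EBImage::Image(arr, colormode = "Color"), path)
  invisible(path)
}
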