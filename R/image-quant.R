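#' Reservoir image and plasma mask containers
#'
#' Minimal containers for image-based plasma quantification: an 8-bit
#' greyscale snapshot of the reservoir, and the binary plasma mask segmented
#' from it. Pixel size is supplied explicitly (micrometres per pixel edge);
#' it is never read from image metadata.
#'
#' @param image Numeric matrix of intensities in \[0, 255\].
#' @param pixel_size Physical pixel edge (micrometres), positive.
#' @param timestamp Optional acquisition time (seconds).
#'
#' @return `reservoir_image()` returns a `reservoir_image`; `plasma_mask()`
#'   returns a `plasma_mask`.
#' @export
reservoir_image <- function(image, pixel_size, timestamp = NA_real_) {
  if (!is.matrix(image) || length(image) == 0) abort("`image` must be a nonempty matrix.")
  if (min(image) < 0 || max(image) > 255) abort("Intensities must lie in [0, 255].")
  if (pixel_size <= 0) abort("`pixel_size` must be > 0.")
  structure(
    list(image = image, pixel_size = pixel_size, timestamp = timestamp),
    class = "reservoir_image"
  )
}

#' @rdname reservoir_image
#' @param mask Logical matrix, `TRUE` where plasma is present.
#' @export
plasma_mask <- function(mask, pixel_size) {
  if (!is.matrix(mask) || length(mask) == 0) abort("`mask` must be a nonempty matrix.")
  if (pixel_size <= 0) abort("`pixel_size` must be > 0.")
  structure(
    list(mask = mask > 0, pixel_size = pixel_size),
    class = "plasma_mask"
  )
}

#' Read an 8-bit greyscale PNG as a reservoir image
#'
#' @param path Path to a PNG file.
#' @param pixel_size Pixel edge in micrometres (not read from metadata).
#' @param timestamp Optional acquisition time (seconds).
#' @return A [reservoir_image()].
#' @export
read_reservoir_image <- function(path, pixel_size, timestamp = NA_real_) {
  if (!file.exists(path)) abort(sprintf("Image file not found: %s", path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1] # first channel of RGB(A)
  reservoir_image(round(img * 255), pixel_size, timestamp)
}

#' @rdname read_reservoir_image
#' @param img A [reservoir_image()] to write.
#' @export
write_reservoir_image <- function(img, path) {
  stopifnot(inherits(img, "reservoir_image"))
  png::writePNG(pmin(pmax(img$image / 255, 0), 1), target = path)
  invisible(path)
}

#' Segment the plasma region of a reservoir image
#'
#' Thresholds the image into a binary plasma mask. Plasma is rendered bright
#' in this package's synthetic images; set `invert = TRUE` for imagery where
#' the liquid is the dark phase. `threshold = "auto"` picks the Otsu threshold
#' of the bimodal intensity histogram and refuses near-uniform images, for
#' which no foreground/background split exists.
#'
#' @param img A [reservoir_image()].
#' @param threshold Numeric intensity in \[0, 255\], or `"auto"` (Otsu).
#' @param invert If `TRUE`, plasma is taken as the dark phase.
#'
#' @return A [plasma_mask()] with the image's pixel size.
#' @export
segment_plasma <- function(img, threshold = "auto", invert = FALSE) {
  stopifnot(inherits(img, "reservoir_image"))
  x <- img$image
  if (identical(threshold, "auto")) {
    if (diff(range(x)) < 8) {
      abort("Image is (near-)uniform: no bimodal histogram to threshold automatically.")
    }
    threshold <- EBImage::otsu(x / 255, range = c(0, 1), levels = 256) * 255
  }
  if (!is.numeric(threshold) || threshold < 0 || threshold > 255) {
    abort("`threshold` must be \"auto\" or an intensity in [0, 255].")
  }
  m <- if (invert) x <= threshold else x >= threshold
  plasma_mask(m, img$pixel_size)
}

#' Plasma area of a binary mask
#'
#' True-pixel count times the pixel area, converted to mm^2
#' (1 pixel = `pixel_size^2` um^2 = `pixel_size^2 * 1e-6` mm^2).
#'
#' @param mask A [plasma_mask()].
#' @return Plasma area S in mm^2.
#' @examples
#' m <- plasma_mask(matrix(TRUE, 20, 20), pixel_size = 50)
#' plasma_area(m) # 400 px * 2500 um^2 = 1 mm^2
#' @export
plasma_area <- function(mask) {
  stopifnot(inherits(mask, "plasma_mask"))
  sum(mask$mask) * mask$pixel_size^2 * 1e-6
}

#' Plasma volume from segmented area and channel height
#'
#' The reservoir channel has constant height, so the plasma volume is simply
#' area times height: `V = S * h`, with 1 mm^2 x 1 um = 1e-3 uL.
#'
#' @param S Plasma area (mm^2), non-negative. Vectorised.
#' @param h Channel height (micrometres), positive.
#' @return Plasma volume in uL.
#' @examples
#' volume_from_area(125, 80) # 10 uL
#' @export
volume_from_area <- function(S, h) {
  if (any(S < 0)) abort("`S` must be >= 0.")
  if (h <= 0) abort("`h` must be > 0.")
  S * h * 1e-3
}

#' Assemble a filtration curve from a time series of reservoir images
#'
#' Segments each image, converts plasma area to volume via `V = S * h`, and
#' returns the resulting (time, volume) series as a [filtration_curve()].
#'
#' @param images List of [reservoir_image()]s with timestamps, in
#'   chronological order.
#' @param h Channel height (micrometres).
#' @param area_mm2 Effective filtration area of the imaged device (mm^2),
#'   recorded on the curve for downstream fitting.
#' @param threshold Passed to [segment_plasma()]. Default `"auto"`.
#' @param invert Passed to [segment_plasma()].
#'
#' @return A [filtration_curve()].
#' @export
curve_from_images <- function(images, h, area_mm2, threshold = "auto", invert = FALSE) {
  if (length(images) < 3) abort("Need at least 3 images to form a curve.")
  ts <- vapply(images, function(im) {
    stopifnot(inherits(im, "reservoir_image"))
    as.numeric(im$timestamp)
  }, numeric(1))
  if (anyNA(ts)) abort("All images must carry a timestamp.")
  if (any(diff(ts) <= 0)) abort("Image timestamps must be strictly increasing.")
  vols <- vapply(images, function(im) {
    volume_from_area(plasma_area(segment_plasma(im, threshold, invert)), h)
  }, numeric(1))
  filtration_curve(ts, vols, area_mm2 = area_mm2, label = "from images")
}
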