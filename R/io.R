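## Raster readers/writers (PNG, TIFF) and ROI sidecar files.  Images are
## 8-bit in memory; 16-bit inputs are linearly rescaled to 8-bit with a
## warning, since every downstream procedure is defined on 8-bit data.

#' Read an image file
#'
#' Reads a PNG or TIFF raster. Grayscale files yield a numeric matrix,
#' colour files an H x W x 3 array, both with 8-bit integer values.
#' An alpha channel, if present, is dropped. 16-bit inputs are rescaled
#' linearly so that the full 16-bit range maps onto \[0, 255\], with a
#' warning.
#'
#' @param path file path; format inferred from the extension
#'   (`.png`, `.tif`, `.tiff`).
#' @return numeric matrix (gray) or H x W x 3 array (RGB), values in
#'   \[0, 255\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    depth <- png_bit_depth(path)
    if (depth > 8L)
      warning(sprintf("%d-bit PNG rescaled to 8-bit", depth), call. = FALSE)
    x <- png::readPNG(path)      # normalized to [0, 1] whatever the depth
    from01(x)
  } else if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, as.is = TRUE)   # raw integer sample values
    mx <- max(x)
    if (mx > 255) {
      warning("16-bit TIFF rescaled to 8-bit", call. = FALSE)
      x <- x / 65535
    } else {
      x <- x / 255
    }
    from01(x)
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
}

# bit depth is byte 25 of the PNG stream (IHDR)
png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 25L)
  as.integer(hdr[25L])
}

from01 <- function(x) {
  if (length(dim(x)) == 3L && dim(x)[3L] >= 3L) x <- x[, , 1:3, drop = FALSE]
  if (length(dim(x)) == 3L && dim(x)[3L] == 1L) x <- x[, , 1L]
  quantize8(x * 255)
}

#' Write an image file
#'
#' Writes an 8-bit grayscale matrix or RGB array as PNG or TIFF; the
#' round trip through [read_image()] is lossless.
#'
#' @param image numeric matrix or H x W x 3 array, values in \[0, 255\].
#' @param path output path (`.png`, `.tif` or `.tiff`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  if (is.matrix(image)) assert_gray(image) else assert_rgb(image)
  x <- image / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(x, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(x, path, bits.per.sample = 8L)
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' Write / read an ROI sidecar file
#'
#' The sidecar is a JSON object with optional members `rects` (list of
#' \{top, left, height, width\}), `polygons` (list of \{x: \[...\],
#' y: \[...\]\}) and `scale_px_per_cm`. All coordinates are 0-based pixel
#' coordinates, x = column, y = row, origin top-left.
#'
#' @param rois list with elements `rects` (list of [rect_roi()]),
#'   `polygons` (list of [polygon_roi()]) and optional `scale_px_per_cm`.
#' @param path JSON file path.
#' @return `write_roi_json()`: `path` invisibly; `read_roi_json()`: the
#'   `rois` list.
#' @export
write_roi_json <- function(rois, path) {
  out <- list(
    rects = lapply(rois$rects %||% list(), function(r)
      list(top = r$top, left = r$left, height = r$height, width = r$width)),
    polygons = lapply(rois$polygons %||% list(), function(p)
      list(x = unname(p$vertices[, 1L]), y = unname(p$vertices[, 2L])))
  )
  if (!is.null(rois$scale_px_per_cm))
    out$scale_px_per_cm <- rois$scale_px_per_cm
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_json
#' @export
read_roi_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  list(
    rects = lapply(x$rects %||% list(), function(r)
      rect_roi(r$top, r$left, r$height, r$width)),
    polygons = lapply(x$polygons %||% list(), function(p)
      polygon_roi(cbind(x = p$x, y = p$y))),
    scale_px_per_cm = x$scale_px_per_cm
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
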