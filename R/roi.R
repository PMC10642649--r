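## Regions of interest: rectangular crops (the hand-cropping step that
## removes scale bar and drops before fractal analysis) and polygonal drop
## outlines (the drop-border selections used for pigment quantification).
## Pixel membership is decided at pixel centres by the even-odd rule, with
## boundary pixels counted as inside, so all counts are bit-stable.

#' Rectangular region of interest
#'
#' Half-open pixel rectangle `[top, top + height) x [left, left + width)`
#' in 0-based image coordinates (x = column, y = row, origin top-left).
#'
#' @param top,left 0-based offsets of the first row/column.
#' @param height,width extent in pixels (positive).
#' @return an object of class `rect_roi`.
#' @export
rect_roi <- function(top, left, height, width) {
  top <- as.integer(top); left <- as.integer(left)
  height <- as.integer(height); width <- as.integer(width)
  if (height < 1L || width < 1L || top < 0L || left < 0L)
    stop("invalid rectangle", call. = FALSE)
  structure(list(top = top, left = left, height = height, width = width),
            class = "rect_roi")
}

#' Polygonal region of interest
#'
#' A simple (non-self-intersecting) closed polygon given by its ordered
#' vertices in 0-based pixel coordinates; the closing edge back to the
#' first vertex is implicit.
#'
#' @param vertices numeric n x 2 matrix (columns x, y), n >= 3.
#' @return an object of class `polygon_roi`.
#' @export
polygon_roi <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L || ncol(vertices) != 2L)
    stop("a polygon needs at least 3 (x, y) vertices", call. = FALSE)
  if (anyNA(vertices)) stop("degenerate polygon", call. = FALSE)
  # degenerate: zero area
  x <- vertices[, 1L]; y <- vertices[, 2L]
  a2 <- abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y))
  if (a2 == 0) stop("degenerate polygon", call. = FALSE)
  colnames(vertices) <- c("x", "y")
  structure(list(vertices = vertices), class = "polygon_roi")
}

#' Crop an image to a rectangular ROI
#'
#' @param image grayscale matrix or RGB array.
#' @param roi a [rect_roi()], fully inside the image.
#' @return image of shape (height, width).
#' @export
crop_rect <- function(image, roi) {
  stopifnot(inherits(roi, "rect_roi"))
  d <- dim(image)
  if (roi$top + roi$height > d[1L] || roi$left + roi$width > d[2L])
    stop("ROI exceeds image bounds", call. = FALSE)
  rows <- roi$top + seq_len(roi$height)
  cols <- roi$left + seq_len(roi$width)
  if (length(d) == 3L) image[rows, cols, , drop = FALSE]
  else image[rows, cols, drop = FALSE]
}

#' Which pixel centres fall inside a polygon
#'
#' Even-odd (ray crossing) rule on pixel centres at integer coordinates;
#' pixels whose centre lies exactly on a polygon edge or vertex count as
#' inside.
#'
#' @param roi a [polygon_roi()].
#' @param width,height image extent in pixels.
#' @return logical `height x width` matrix.
#' @keywords internal
polygon_pixel_mask <- function(roi, width, height) {
  v <- roi$vertices
  n <- nrow(v)
  xv <- v[, 1L]; yv <- v[, 2L]
  xv2 <- c(xv[-1L], xv[1L]); yv2 <- c(yv[-1L], yv[1L])
  # restrict to the polygon's bounding box
  x0 <- max(0L, floor(min(xv))); x1 <- min(width - 1L, ceiling(max(xv)))
  y0 <- max(0L, floor(min(yv))); y1 <- min(height - 1L, ceiling(max(yv)))
  out <- matrix(FALSE, height, width)
  if (x1 < x0 || y1 < y0) return(out)
  px <- rep(x0:x1, each = y1 - y0 + 1L)
  py <- rep(y0:y1, times = x1 - x0 + 1L)
  inside <- rep(FALSE, length(px))
  onb <- rep(FALSE, length(px))
  eps <- 1e-9
  for (e in seq_len(n)) {
    ax <- xv[e]; ay <- yv[e]; bx <- xv2[e]; by <- yv2[e]
    # boundary: collinear and within the segment's bounding box
    cross <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
    onseg <- abs(cross) <= eps * (abs(bx - ax) + abs(by - ay) + 1) &
      px >= pmin(ax, bx) - eps & px <= pmax(ax, bx) + eps &
      py >= pmin(ay, by) - eps & py <= pmax(ay, by) + eps
    onb <- onb | onseg
    # crossing test, half-open in y to handle vertices exactly once
    crosses <- ((ay > py) != (by > py))
    if (any(crosses)) {
      xi <- ax + (py - ay) * (bx - ax) / (by - ay)
      inside <- xor(inside, crosses & (px < xi))
    }
  }
  keep <- inside | onb
  out[cbind(py + 1L, px + 1L)] <- keep
  out
}

#' Fill polygonal regions with a constant value
#'
#' Sets every pixel whose centre falls inside any of the polygons to
#' `fill`; used to blank out drops and scale bars before fractal analysis.
#' Pixels outside all polygons are never changed.
#'
#' @param image grayscale matrix.
#' @param rois list of [polygon_roi()] (may be empty).
#' @param fill 8-bit fill value.
#' @return the masked image.
#' @export
mask_out_polygons <- function(image, rois, fill = 0L) {
  assert_gray(image)
  stopifnot(fill >= 0, fill <= 255)
  for (roi in rois) {
    stopifnot(inherits(roi, "polygon_roi"))
    m <- polygon_pixel_mask(roi, ncol(image), nrow(image))
    image[m] <- fill
  }
  image
}

#' Pixel area of a polygon
#'
#' Number of pixel centres inside the polygon (boundary-inclusive even-odd
#' rule). Agrees with the shoelace area to within half the perimeter
#' (discretization bound).
#'
#' @param roi a [polygon_roi()].
#' @return integer pixel count.
#' @export
polygon_area_px <- function(roi) {
  stopifnot(inherits(roi, "polygon_roi"))
  v <- roi$vertices
  w <- ceiling(max(v[, 1L])) + 1L
  h <- ceiling(max(v[, 2L])) + 1L
  sum(polygon_pixel_mask(roi, w, h))
}

#' Pixel scale
#'
#' @param px_per_cm positive number of pixels per centimetre.
#' @return an object of class `pixel_scale`.
#' @export
pixel_scale <- function(px_per_cm) {
  if (!is.numeric(px_per_cm) || length(px_per_cm) != 1L || px_per_cm <= 0)
    stop("px_per_cm must be a positive number", call. = FALSE)
  structure(list(px_per_cm = px_per_cm), class = "pixel_scale")
}

#' Convert a pixel count to an area in square centimetres
#'
#' @param count pixel count (e.g. from [polygon_area_px()]).
#' @param scale a [pixel_scale()].
#' @return area in cm^2.
#' @export
area_cm2 <- function(count, scale) {
  stopifnot(inherits(scale, "pixel_scale"))
  count / scale$px_per_cm^2
}
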