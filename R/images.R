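#' @keywords internal
"_PACKAGE"

## Raster conventions used throughout the package
##
## GrayImage  - numeric matrix, integer values in [0, 255], row-major with
##              origin at the top-left (matrix row 1 = image row y = 0).
## RGBImage   - numeric H x W x 3 array, integer values in [0, 255].
## BinaryMask - logical matrix, TRUE = foreground (counted pixel).
##
## ROI coordinates are 0-based, x = column, y = row, origin top-left; a
## pixel's centre sits at integer (x, y).  R's 1-based matrix indexing is
## an internal detail: pixel (x, y) is m[y + 1, x + 1].

#' Validate a grayscale image
#'
#' @param img object to check.
#' @param arg name used in error messages.
#' @return `img`, invisibly, if valid.
#' @keywords internal
assert_gray <- function(img, arg = "image") {
  if (!is.matrix(img) || !is.numeric(img) || length(img) == 0L)
    stop(sprintf("`%s` must be a non-empty numeric matrix", arg), call. = FALSE)
  rng <- range(img)
  if (is.na(rng[1L]) || rng[1L] < 0 || rng[2L] > 255)
    stop(sprintf("`%s` must have values in [0, 255]", arg), call. = FALSE)
  invisible(img)
}

#' @rdname assert_gray
#' @keywords internal
assert_rgb <- function(img, arg = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3L] != 3L)
    stop(sprintf("`%s` must be an H x W x 3 array", arg), call. = FALSE)
  rng <- range(img)
  if (is.na(rng[1L]) || rng[1L] < 0 || rng[2L] > 255)
    stop(sprintf("`%s` must have values in [0, 255]", arg), call. = FALSE)
  invisible(img)
}

#' @rdname assert_gray
#' @keywords internal
assert_mask <- function(img, arg = "mask") {
  if (!is.matrix(img) || !is.logical(img) || length(img) == 0L)
    stop(sprintf("`%s` must be a non-empty logical matrix", arg), call. = FALSE)
  invisible(img)
}

#' Quantize a floating-point raster to 8-bit
#'
#' Rounds half away from zero (the convention used at every module
#' boundary) and clips to \[0, 255\].
#'
#' @param x numeric matrix or array.
#' @return same shape, integer-valued, in \[0, 255\].
#' @keywords internal
quantize8 <- function(x) {
  x <- pmin(pmax(x, 0), 255)
  # round half away from zero; base round() is round-half-even
  s <- sign(x)
  s * floor(abs(x) + 0.5)
}

#' Replicate-pad a matrix
#'
#' @param m numeric matrix.
#' @param p non-negative integer pad width (same on all four sides).
#' @return padded matrix of size (nrow + 2p) x (ncol + 2p).
#' @keywords internal
pad_replicate <- function(m, p) {
  if (p == 0L) return(m)
  ri <- c(rep(1L, p), seq_len(nrow(m)), rep(nrow(m), p))
  ci <- c(rep(1L, p), seq_len(ncol(m)), rep(ncol(m), p))
  m[ri, ci, drop = FALSE]
}
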