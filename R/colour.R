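## Red pigment quantification on the CIELAB a* channel.  The RGB scene is
## converted sRGB (D65) -> CIELAB and re-encoded to the 8-bit convention
## used by ImageJ Lab stacks (L* scaled to 0-255; a*, b* offset by +128 and
## clipped), a single Huang threshold is computed on the whole image's
## a-plane histogram, and pixels above it are counted as red inside each
## polygonal drop ROI.

#' Convert an RGB image to an 8-bit CIELAB stack
#'
#' Assumes sRGB with D65 white point. Encoding: L* (0-100) is scaled to
#' 0-255; a* and b* are offset by +128 and clipped to \[0, 255\], so an
#' a-plane value of 128 is the neutral axis (a* = 0) and red pigment maps
#' well above 128.
#'
#' @param image H x W x 3 array, 8-bit values.
#' @return list with matrices `L`, `a`, `b` (8-bit values).
#' @examples
#' img <- array(128, dim = c(2, 2, 3))  # neutral gray
#' rgb_to_lab8(img)$a[1, 1]             # 128
#' @export
rgb_to_lab8 <- function(image) {
  assert_rgb(image)
  d <- dim(image)
  rgb01 <- cbind(as.vector(image[, , 1L]), as.vector(image[, , 2L]),
                 as.vector(image[, , 3L])) / 255
  lab <- grDevices::convertColor(rgb01, from = "sRGB", to = "Lab")
  list(L = matrix(quantize8(lab[, 1L] * 255 / 100), d[1L], d[2L]),
       a = matrix(quantize8(lab[, 2L] + 128), d[1L], d[2L]),
       b = matrix(quantize8(lab[, 3L] + 128), d[1L], d[2L]))
}

#' Quantify red pigment coverage inside drop ROIs
#'
#' One Huang threshold is computed per image from the a-plane histogram
#' (not per drop), pixels strictly above it are classified red, connected
#' red components (8-connectivity) smaller than `min_particle_px` are
#' discarded, and per-drop percentages are taken over the pixels inside
#' each polygon ROI. Drops whose polygon is not fully inside the image are
#' flagged `excluded` with `NA` counts rather than dropped.
#'
#' @param image H x W x 3 RGB array.
#' @param drops list of [polygon_roi()], one per drop.
#' @param min_particle_px minimum red particle size in pixels (default 0,
#'   no size filter).
#' @param threshold a [threshold_method()]; default Huang.
#' @param min_class_separation degenerate-histogram guard: if the mean
#'   a-plane values of the two classes induced by the threshold differ by
#'   less than this (8-bit units), the image has no red class — an
#'   automatic threshold is then merely splitting noise — and every drop
#'   scores zero red pixels. Default 16 (one sixteenth of the 8-bit
#'   range); set to 0 to disable.
#' @return data frame: drop_id, red_pixels, roi_pixels, percent_red,
#'   threshold_used, excluded.
#' @export
quantify_red_in_drops <- function(image, drops, min_particle_px = 0L,
                                  threshold = threshold_method("huang"),
                                  min_class_separation = 16) {
  assert_rgb(image)
  if (length(drops) < 1L) stop("at least one drop ROI is required", call. = FALSE)
  a <- rgb_to_lab8(image)$a
  thr <- compute_threshold(a, threshold)
  red <- a > thr
  if (threshold$name != "fixed" && min_class_separation > 0 && any(red)) {
    sep <- mean(a[red]) - mean(a[!red])
    if (sep < min_class_separation) red[] <- FALSE
  }
  if (min_particle_px > 0L && any(red)) {
    lab <- label_components(red)
    sizes <- tabulate(lab[lab > 0L])
    red <- matrix(lab %in% which(sizes >= min_particle_px),
                  nrow(red), ncol(red))
  }
  H <- nrow(a); W <- ncol(a)
  rows <- lapply(seq_along(drops), function(k) {
    roi <- drops[[k]]
    stopifnot(inherits(roi, "polygon_roi"))
    v <- roi$vertices
    if (min(v[, 1L]) < 0 || max(v[, 1L]) > W - 1 ||
        min(v[, 2L]) < 0 || max(v[, 2L]) > H - 1) {
      return(data.frame(drop_id = k, red_pixels = NA_integer_,
                        roi_pixels = NA_integer_, percent_red = NA_real_,
                        threshold_used = thr, excluded = TRUE))
    }
    inside <- polygon_pixel_mask(roi, W, H)
    n_roi <- sum(inside)
    n_red <- sum(red & inside)
    data.frame(drop_id = k, red_pixels = n_red, roi_pixels = n_roi,
               percent_red = 100 * n_red / n_roi, threshold_used = thr,
               excluded = FALSE)
  })
  do.call(rbind, rows)
}

#' Label 8-connected components of a binary mask
#'
#' Two-pass union-find labeling with 8-connectivity (the connectivity of
#' ImageJ particle analysis).
#'
#' @param mask logical matrix.
#' @return integer matrix; 0 = background, components numbered 1..n in
#'   raster order of first appearance.
#' @export
label_components <- function(mask) {
  assert_mask(mask)
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nxt <- 0L
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (!mask[r, c]) next
    nb <- integer(0)
    if (r > 1L) {
      if (c > 1L && lab[r - 1L, c - 1L] > 0L) nb <- c(nb, lab[r - 1L, c - 1L])
      if (lab[r - 1L, c] > 0L) nb <- c(nb, lab[r - 1L, c])
      if (c < W && lab[r - 1L, c + 1L] > 0L) nb <- c(nb, lab[r - 1L, c + 1L])
    }
    if (c > 1L && lab[r, c - 1L] > 0L) nb <- c(nb, lab[r, c - 1L])
    if (length(nb) == 0L) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      lab[r, c] <- nxt
    } else {
      roots <- unique(vapply(nb, find, integer(1)))
      keep <- min(roots)
      lab[r, c] <- keep
      for (q in roots) parent[q] <- keep
    }
  }
  if (nxt == 0L) return(lab)
  # resolve, then renumber by row-major order of first appearance
  roots <- vapply(seq_len(nxt), find, integer(1))
  idx <- which(lab > 0L)
  lab[idx] <- roots[lab[idx]]
  rm_ord <- order(row(lab)[idx], col(lab)[idx])
  uniq <- unique(lab[idx][rm_ord])
  remap <- integer(nxt)
  remap[uniq] <- seq_along(uniq)
  lab[idx] <- remap[lab[idx]]
  lab
}
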