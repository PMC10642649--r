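## Edge-preserving smoothing, edge detection and binarization: the image
## treatment that turns a raw grayscale micrograph of hyphae into the
## binary mask fed to box counting.  All filters work in floating point
## internally and quantize to 8-bit (round half away from zero) only at
## the module boundary; borders are replicate-padded everywhere so the
## image edge never produces spurious gradients that would inflate box
## counts.

#' Kuwahara filter configuration
#'
#' @param variant `"classic"` (four overlapping square quadrants) or
#'   `"linear"` (oriented line segments, suited to thin filaments).
#' @param window odd integer >= 3: the square window side (classic) or the
#'   segment length L (linear).
#' @param n_orientations number of line orientations (linear only), >= 4;
#'   angles are k*pi/n for k = 0, ..., n-1.
#' @return an object of class `kuwahara_config`.
#' @export
kuwahara_config <- function(variant = c("linear", "classic"), window = 5L,
                            n_orientations = 8L) {
  variant <- match.arg(variant)
  window <- as.integer(window)
  n_orientations <- as.integer(n_orientations)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3", call. = FALSE)
  if (variant == "linear" && n_orientations < 4L)
    stop("n_orientations must be >= 4", call. = FALSE)
  structure(list(variant = variant, window = window,
                 n_orientations = n_orientations),
            class = "kuwahara_config")
}

#' Kuwahara edge-preserving smoothing
#'
#' Replaces each pixel with the mean of the least-variance local region
#' among a set of regions containing the pixel. The classic variant uses
#' the four overlapping ceiling(w/2)-square quadrants of a w x w window;
#' the linear variant uses line segments of length `window` at
#' `n_orientations` orientations through the pixel, which preserves thin
#' bright filaments. Ties are broken by the lowest region index (quadrants
#' in order top-left, top-right, bottom-left, bottom-right; orientations in
#' order k = 0, 1, ...). Output values are convex combinations of input
#' values, so the range never expands.
#'
#' @param image grayscale matrix (values in \[0, 255\]).
#' @param cfg a [kuwahara_config()].
#' @return filtered grayscale matrix, 8-bit values.
#' @export
kuwahara <- function(image, cfg = kuwahara_config()) {
  assert_gray(image)
  stopifnot(inherits(cfg, "kuwahara_config"))
  if (cfg$window > min(dim(image)))
    stop("window larger than image", call. = FALSE)
  out <- if (cfg$variant == "classic")
    kuwahara_classic(image, cfg$window)
  else
    kuwahara_linear(image, cfg$window, cfg$n_orientations)
  quantize8(out)
}

# classic variant: integral-image box sums over the four quadrants
kuwahara_classic <- function(img, w) {
  q <- (w + 1L) %/% 2L            # quadrant side, quadrants overlap at centre
  p <- q - 1L
  pad <- pad_replicate(img, p)
  I1 <- integral_image(pad)
  I2 <- integral_image(pad * pad)
  H <- nrow(img); W <- ncol(img)
  # quadrant top-left corners relative to the centre pixel, order TL TR BL BR
  offs <- list(c(-p, -p), c(-p, 0L), c(0L, -p), c(0L, 0L))
  best_var <- matrix(Inf, H, W)
  best_mean <- matrix(0, H, W)
  n <- q * q
  for (o in offs) {
    r0 <- p + o[1L]; c0 <- p + o[2L]   # 0-based top-left in padded image
    s1 <- box_sum(I1, r0, c0, q, H, W)
    s2 <- box_sum(I2, r0, c0, q, H, W)
    mu <- s1 / n
    va <- s2 / n - mu * mu
    take <- va < best_var - 1e-9       # strict: earlier quadrant wins ties
    best_mean[take] <- mu[take]
    best_var[take] <- va[take]
  }
  best_mean
}

# summed-area table with a zero first row/column
integral_image <- function(m) {
  I <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
  I[-1L, -1L] <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))
  I
}

# sums of q x q boxes whose top-left is at padded 0-based (r0 + i, c0 + j)
# for output pixels (i, j), i = 0..H-1, j = 0..W-1
box_sum <- function(I, r0, c0, q, H, W) {
  ri <- r0 + seq_len(H); ci <- c0 + seq_len(W)
  I[ri + q - 1L + 1L, ci + q - 1L + 1L, drop = FALSE] -
    I[ri, ci + q - 1L + 1L, drop = FALSE] -
    I[ri + q - 1L + 1L, ci, drop = FALSE] +
    I[ri, ci, drop = FALSE]
}

# linear variant: mean/variance along oriented line segments through the
# pixel; implemented as sums of shifted replicate-padded copies
kuwahara_linear <- function(img, L, n_or) {
  half <- (L - 1L) %/% 2L
  pad <- pad_replicate(img, half)
  H <- nrow(img); W <- ncol(img)
  rows <- half + seq_len(H); cols <- half + seq_len(W)
  ts <- seq(-half, half)
  best_var <- matrix(Inf, H, W)
  best_mean <- matrix(0, H, W)
  for (k in seq_len(n_or) - 1L) {
    th <- k * pi / n_or
    dx <- round(ts * cos(th)); dy <- round(ts * sin(th))
    off <- unique(cbind(dy, dx))
    m <- nrow(off)
    s1 <- matrix(0, H, W); s2 <- matrix(0, H, W)
    for (i in seq_len(m)) {
      sh <- pad[rows + off[i, 1L], cols + off[i, 2L], drop = FALSE]
      s1 <- s1 + sh
      s2 <- s2 + sh * sh
    }
    mu <- s1 / m
    va <- s2 / m - mu * mu
    take <- va < best_var - 1e-9
    best_mean[take] <- mu[take]
    best_var[take] <- va[take]
  }
  best_mean
}

#' Sobel gradient magnitude
#'
#' Convolves with the standard 3 x 3 Sobel kernels
#' (horizontal `[[-1,0,1],[-2,0,2],[-1,0,1]]` and its transpose), returns
#' `sqrt(Gx^2 + Gy^2)` clipped to \[0, 255\] and rounded. Borders are
#' replicate-padded; the output is invariant under intensity offsets
#' (before clipping).
#'
#' @param image grayscale matrix, at least 3 x 3.
#' @return gradient-magnitude image, 8-bit values.
#' @export
sobel_magnitude <- function(image) {
  assert_gray(image)
  if (nrow(image) < 3L || ncol(image) < 3L)
    stop("image must be at least 3 x 3", call. = FALSE)
  p <- pad_replicate(image, 1L)
  H <- nrow(image); W <- ncol(image)
  sh <- function(dy, dx) p[1L + dy + seq_len(H), 1L + dx + seq_len(W), drop = FALSE]
  gx <- -sh(-1L, -1L) + sh(-1L, 1L) - 2 * sh(0L, -1L) + 2 * sh(0L, 1L) -
    sh(1L, -1L) + sh(1L, 1L)
  gy <- -sh(-1L, -1L) - 2 * sh(-1L, 0L) - sh(-1L, 1L) +
    sh(1L, -1L) + 2 * sh(1L, 0L) + sh(1L, 1L)
  quantize8(sqrt(gx * gx + gy * gy))
}

#' Threshold method specification
#'
#' @param name `"isodata"` (iterative intermeans, the ImageJ mask default),
#'   `"otsu"` (maximal between-class variance), `"huang"` (minimal fuzzy
#'   entropy) or `"fixed"`.
#' @param fixed_value 8-bit threshold, required when `name = "fixed"`.
#' @return an object of class `threshold_method`.
#' @export
threshold_method <- function(name = c("isodata", "otsu", "huang", "fixed"),
                             fixed_value = NULL) {
  name <- match.arg(name)
  if (name == "fixed") {
    if (is.null(fixed_value)) stop("fixed requires fixed_value", call. = FALSE)
    stopifnot(fixed_value >= 0, fixed_value <= 255)
  }
  structure(list(name = name, fixed_value = fixed_value),
            class = "threshold_method")
}

#' Compute an automatic 8-bit threshold
#'
#' Candidate thresholds t run over the occupied gray range; the foreground
#' is the class above t (see [binarize()]). Methods:
#' \describe{
#'   \item{isodata}{iterate t until it equals the rounded midpoint of the
#'     means of the two classes it induces.}
#'   \item{otsu}{maximize the between-class variance
#'     w0*w1*(mu0 - mu1)^2.}
#'   \item{huang}{Huang & Wang fuzzy thresholding: with class means
#'     m0(t), m1(t) and C = g_max - g_min, each gray level g has membership
#'     mu(g) = 1 / (1 + |g - m(g, t)| / C); choose t minimizing the Shannon
#'     fuzziness S(t) = sum_g h(g) * (-mu log mu - (1 - mu) log(1 - mu)).}
#' }
#' Ties are broken toward the smallest t.
#'
#' @param image grayscale matrix.
#' @param method a [threshold_method()].
#' @return integer threshold in \[0, 255\].
#' @export
compute_threshold <- function(image, method = threshold_method("isodata")) {
  assert_gray(image)
  stopifnot(inherits(method, "threshold_method"))
  if (method$name == "fixed") return(as.integer(method$fixed_value))
  h <- tabulate(as.integer(image) + 1L, nbins = 256L)
  g <- 0:255
  occ <- which(h > 0L)
  if (length(occ) < 2L) stop("degenerate histogram", call. = FALSE)
  gmin <- occ[1L] - 1L
  gmax <- occ[length(occ)] - 1L
  switch(method$name,
    isodata = threshold_isodata(h, gmin, gmax),
    otsu = threshold_otsu(h, gmin, gmax),
    huang = threshold_huang(h, gmin, gmax))
}

threshold_isodata <- function(h, gmin, gmax) {
  g <- 0:255
  t <- (gmin + gmax) %/% 2L
  seen <- integer(0)
  repeat {
    lo <- g <= t
    m0 <- sum(h[lo] * g[lo]) / sum(h[lo])
    m1 <- sum(h[!lo] * g[!lo]) / sum(h[!lo])
    tn <- as.integer(floor((m0 + m1) / 2))
    tn <- min(max(tn, gmin), gmax - 1L)
    if (tn == t) return(t)
    if (tn %in% seen) return(min(t, tn))   # cycle guard: smallest t wins
    seen <- c(seen, t)
    t <- tn
  }
}

threshold_otsu <- function(h, gmin, gmax) {
  g <- 0:255
  cand <- gmin:(gmax - 1L)
  n <- sum(h)
  csum <- cumsum(h)            # csum[t+1] = #pixels <= t
  cmu <- cumsum(h * g)
  w0 <- csum[cand + 1L] / n
  w1 <- 1 - w0
  mu0 <- cmu[cand + 1L] / csum[cand + 1L]
  mu1 <- (cmu[256L] - cmu[cand + 1L]) / (n - csum[cand + 1L])
  bcv <- w0 * w1 * (mu0 - mu1)^2
  cand[which.max(bcv)]         # which.max takes the first (smallest t)
}

threshold_huang <- function(h, gmin, gmax) {
  cand <- gmin:(gmax - 1L)
  S <- vapply(cand, function(t) huang_fuzziness(h, t, gmin, gmax),
              numeric(1))
  cand[which.min(S)]
}

# Shannon fuzziness of the two-class partition at threshold t
huang_fuzziness <- function(h, t, gmin, gmax) {
  g <- 0:255
  C <- gmax - gmin
  lo <- g <= t
  m0 <- sum(h[lo] * g[lo]) / sum(h[lo])
  m1 <- sum(h[!lo] * g[!lo]) / sum(h[!lo])
  m <- ifelse(lo, m0, m1)
  mu <- 1 / (1 + abs(g - m) / C)
  f <- -mu * log(mu) - (1 - mu) * log1p(-mu)
  f[mu >= 1 - 1e-12] <- 0      # 0 log 0 = 0 at exact membership
  sum(h * f)
}

#' Binarize a grayscale image
#'
#' @param image grayscale matrix.
#' @param threshold 8-bit threshold.
#' @param polarity `"above_is_fg"`: foreground = pixels strictly greater
#'   than the threshold (the convention for bright filament edges on a dark
#'   background); `"below_is_fg"`: foreground = pixels strictly less.
#' @return logical matrix (TRUE = foreground).
#' @export
binarize <- function(image, threshold, polarity = c("above_is_fg", "below_is_fg")) {
  assert_gray(image)
  polarity <- match.arg(polarity)
  if (polarity == "above_is_fg") image > threshold else image < threshold
}
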