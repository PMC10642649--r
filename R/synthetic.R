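## Synthetic-data generators: branching mycelium images, analytic fractal
## fixtures with known dimension, and pigmented drop scenes with known red
## fraction.  All generators are pure functions of (params, seed): the seed
## is a required field and the global RNG state is never touched
## (withr::with_seed).

#' Parameters for the mycelium growth simulator
#'
#' Describes a simple 2D tip-growth model of a mycelium spanning the gap
#' between two media drops: tips start on the left edge heading right, each
#' iteration every active tip advances by `step_len_px` with a Gaussian
#' heading perturbation and may spawn a lateral branch. Strokes are rendered
#' at `fg_level` on a `bg_level` background, then a linear illumination
#' gradient and additive Gaussian noise emulate uneven microscope
#' illumination and sensor noise.
#'
#' @param width_px,height_px canvas size in pixels (>= 64).
#' @param n_tips0 number of initial tips on the left edge.
#' @param step_len_px tip advance per iteration, in pixels.
#' @param jitter_sd_rad s.d. of the per-step heading perturbation (radians).
#' @param branch_prob probability, per tip per step, of spawning a branch.
#' @param branch_angle_rad mean absolute angle of a new branch relative to
#'   its parent (radians); the sign is random.
#' @param hypha_width_px stroke width in pixels (>= 1).
#' @param n_steps number of growth iterations (>= 1).
#' @param fg_level,bg_level 8-bit stroke and background intensities,
#'   0 <= bg_level < fg_level <= 255.
#' @param noise_sd s.d. of additive Gaussian pixel noise (8-bit units).
#' @param illum_amp peak-to-peak amplitude of a horizontal linear
#'   illumination gradient (8-bit units).
#' @param max_tips cap on simultaneously active tips; branching is
#'   suppressed while the cap is reached (crowding limit).
#' @param seed integer RNG seed (required; no hidden global RNG).
#' @return an object of class `mycelium_params`.
#' @examples
#' p <- mycelium_params(seed = 1)
#' sim <- simulate_mycelium(p)
#' dim(sim$image)
#' @export
mycelium_params <- function(width_px = 384L, height_px = 384L,
                            n_tips0 = 3L, step_len_px = 4,
                            jitter_sd_rad = 0.2, branch_prob = 0.05,
                            branch_angle_rad = 0.6, hypha_width_px = 2L,
                            n_steps = 110L, fg_level = 200L, bg_level = 30L,
                            noise_sd = 10, illum_amp = 30,
                            max_tips = 60L, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  p <- list(width_px = as.integer(width_px), height_px = as.integer(height_px),
            n_tips0 = as.integer(n_tips0), step_len_px = step_len_px,
            jitter_sd_rad = jitter_sd_rad, branch_prob = branch_prob,
            branch_angle_rad = branch_angle_rad,
            hypha_width_px = as.integer(hypha_width_px),
            n_steps = as.integer(n_steps), fg_level = as.integer(fg_level),
            bg_level = as.integer(bg_level), noise_sd = noise_sd,
            illum_amp = illum_amp, max_tips = as.integer(max_tips),
            seed = as.integer(seed))
  if (p$width_px < 64L || p$height_px < 64L)
    stop("canvas must be at least 64 x 64", call. = FALSE)
  if (p$branch_prob < 0 || p$branch_prob > 1)
    stop("branch_prob must lie in [0, 1]", call. = FALSE)
  if (!(p$bg_level >= 0L && p$bg_level < p$fg_level && p$fg_level <= 255L))
    stop("need 0 <= bg_level < fg_level <= 255", call. = FALSE)
  if (p$n_steps < 1L || p$step_len_px <= 0)
    stop("empty simulation", call. = FALSE)
  if (p$n_tips0 < 1L) stop("empty simulation", call. = FALSE)
  class(p) <- "mycelium_params"
  p
}

#' Simulate a mycelium-like image
#'
#' Runs the tip-growth model of [mycelium_params()] and renders it as an
#' 8-bit grayscale image. Tips leaving the canvas are terminated (bounded
#' field of view, no wraparound). The returned skeleton mask records every
#' stroked pixel (after width dilation, before illumination and noise).
#'
#' @param params a [mycelium_params()] object.
#' @return list with `image` (numeric matrix, 8-bit values), `skeleton`
#'   (logical matrix), and `params`.
#' @export
simulate_mycelium <- function(params) {
  stopifnot(inherits(params, "mycelium_params"))
  p <- params
  withr::with_seed(p$seed, {
    H <- p$height_px; W <- p$width_px
    stroke <- matrix(FALSE, H, W)
    # tip state in 0-based pixel coordinates (x = column, y = row)
    x <- rep(0, p$n_tips0)
    y <- (seq_len(p$n_tips0) / (p$n_tips0 + 1)) * (H - 1)
    theta <- rep(0, p$n_tips0)           # heading right
    mark <- function(px, py) {
      ix <- round(px); iy <- round(py)
      keep <- ix >= 0 & ix <= W - 1 & iy >= 0 & iy <= H - 1
      stroke[cbind(iy[keep] + 1L, ix[keep] + 1L)] <<- TRUE
    }
    mark(x, y)
    n_sub <- max(2L, ceiling(p$step_len_px) + 1L)  # <=1 px sample spacing
    tt <- seq(0, 1, length.out = n_sub)
    for (step in seq_len(p$n_steps)) {
      n <- length(x)
      if (n == 0L) break
      theta <- theta + stats::rnorm(n, 0, p$jitter_sd_rad)
      nx <- x + p$step_len_px * cos(theta)
      ny <- y + p$step_len_px * sin(theta)
      # rasterize each segment by dense sampling (8-connected strokes)
      sx <- outer(tt, nx - x) + rep(x, each = n_sub)
      sy <- outer(tt, ny - y) + rep(y, each = n_sub)
      mark(as.vector(sx), as.vector(sy))
      # branching (suppressed at the tip cap), then advance, then cull
      room <- max(0L, p$max_tips - n)
      b <- which(stats::runif(n) < p$branch_prob)
      if (length(b) > room) b <- b[seq_len(room)]
      if (length(b) > 0L) {
        sgn <- sample(c(-1, 1), length(b), replace = TRUE)
        x <- c(nx, nx[b]); y <- c(ny, ny[b])
        theta <- c(theta, theta[b] + sgn * p$branch_angle_rad)
      } else {
        x <- nx; y <- ny
      }
      alive <- x >= 0 & x <= W - 1 & y >= 0 & y <= H - 1
      x <- x[alive]; y <- y[alive]; theta <- theta[alive]
    }
    skeleton <- dilate_square(stroke, p$hypha_width_px)
    img <- matrix(p$bg_level, H, W)
    img[skeleton] <- p$fg_level
    if (p$illum_amp != 0) {
      grad <- p$illum_amp * ((col(img) - 1) / (W - 1) - 0.5)
      img <- pmin(pmax(img + grad, 0), 255)
    }
    if (p$noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, p$noise_sd)
    list(image = quantize8(img), skeleton = skeleton, params = p)
  })
}

# Dilate a logical mask by a w x w square structuring element whose
# reference pixel is at offset floor((w-1)/2); w = 1 is the identity.
dilate_square <- function(mask, w) {
  if (w <= 1L) return(mask)
  off <- seq_len(w) - 1L - (w - 1L) %/% 2L
  H <- nrow(mask); W <- ncol(mask)
  fg <- which(mask, arr.ind = TRUE)
  out <- matrix(FALSE, H, W)
  for (dy in off) for (dx in off) {
    r <- fg[, 1L] + dy; c <- fg[, 2L] + dx
    keep <- r >= 1L & r <= H & c >= 1L & c <= W
    out[cbind(r[keep], c[keep])] <- TRUE
  }
  out
}

#' Render an analytic fractal fixture of known dimension
#'
#' Constructs exact binary masks whose box-counting dimension is known in
#' closed form, for validating the estimator: a 1-pixel horizontal line
#' (dimension 1), a filled square (dimension 2), the Sierpinski carpet
#' (dimension log 8 / log 3), and seeded random dust.
#'
#' @param kind one of `"line"`, `"filled_square"`, `"sierpinski_carpet"`,
#'   `"random_dust"`.
#' @param size_px side length in pixels; for the carpet it must equal
#'   `3^level`.
#' @param level recursion depth (carpet only).
#' @param density occupancy fraction in (0, 1\] (dust only).
#' @param seed integer seed (dust only).
#' @return list with `mask` (logical matrix) and `dimension` (theoretical
#'   box-counting dimension, `NA` for dust).
#' @examples
#' carpet <- render_fractal("sierpinski_carpet", level = 3)
#' sum(carpet$mask)  # 8^3 = 512
#' @export
render_fractal <- function(kind = c("line", "filled_square",
                                    "sierpinski_carpet", "random_dust"),
                           size_px = NULL, level = NULL,
                           density = NULL, seed = NULL) {
  kind <- match.arg(kind)
  switch(kind,
    line = {
      if (is.null(size_px)) stop("size_px is required", call. = FALSE)
      m <- matrix(FALSE, size_px, size_px)
      m[(size_px + 1L) %/% 2L, ] <- TRUE
      list(mask = m, dimension = 1)
    },
    filled_square = {
      if (is.null(size_px)) stop("size_px is required", call. = FALSE)
      list(mask = matrix(TRUE, size_px, size_px), dimension = 2)
    },
    sierpinski_carpet = {
      if (is.null(level)) stop("level is required for the carpet", call. = FALSE)
      if (is.null(size_px)) size_px <- 3L^level
      if (size_px != 3L^level)
        stop("sierpinski_carpet requires size_px = 3^level", call. = FALSE)
      list(mask = carpet_mask(level), dimension = log(8) / log(3))
    },
    random_dust = {
      if (is.null(size_px) || is.null(density) || is.null(seed))
        stop("random_dust requires size_px, density and seed", call. = FALSE)
      stopifnot(density > 0, density <= 1)
      withr::with_seed(as.integer(seed), {
        m <- matrix(FALSE, size_px, size_px)
        n <- max(1L, floor(density * size_px^2))
        m[sample.int(size_px^2, n)] <- TRUE
        list(mask = m, dimension = NA_real_)
      })
    })
}

# Sierpinski carpet by recursive removal of centre ninths.
carpet_mask <- function(level) {
  m <- matrix(TRUE, 1L, 1L)
  for (k in seq_len(level)) {
    s <- nrow(m)
    big <- matrix(FALSE, 3L * s, 3L * s)
    for (i in 0:2) for (j in 0:2) {
      if (i == 1 && j == 1) next
      big[i * s + seq_len(s), j * s + seq_len(s)] <- m
    }
    m <- big
  }
  m
}

#' Parameters for a pigmented drop scene
#'
#' A bright background with circular media drops; inside each drop a stated
#' fraction of interior pixels is painted with a red pigment colour. The
#' exact painted fraction (after flooring to a whole pixel count) is stored
#' as ground truth.
#'
#' @param width_px,height_px canvas size.
#' @param drops data frame (or list of lists) with columns/fields `cx`,
#'   `cy` (centre, 0-based pixel coordinates), `r` (radius, px) and
#'   `red_fraction` in \[0, 1\].
#' @param red_rgb,medium_rgb,bg_rgb length-3 8-bit colour triples.
#' @param noise_sd s.d. of additive Gaussian noise per channel.
#' @param seed integer RNG seed.
#' @return an object of class `drop_scene_params`.
#' @export
drop_scene_params <- function(width_px, height_px, drops,
                              red_rgb = c(180L, 30L, 40L),
                              medium_rgb = c(210L, 200L, 150L),
                              bg_rgb = c(245L, 245L, 245L),
                              noise_sd = 4, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (is.data.frame(drops)) {
    drops <- lapply(seq_len(nrow(drops)), function(i) as.list(drops[i, ]))
  }
  for (d in drops) {
    stopifnot(all(c("cx", "cy", "r", "red_fraction") %in% names(d)))
    if (d$red_fraction < 0 || d$red_fraction > 1)
      stop("red_fraction must lie in [0, 1]", call. = FALSE)
    if (d$cx - d$r < 0 || d$cx + d$r > width_px - 1 ||
        d$cy - d$r < 0 || d$cy + d$r > height_px - 1)
      stop("drops must lie fully inside the canvas", call. = FALSE)
  }
  # pairwise overlap makes the per-drop ground truth ambiguous
  if (length(drops) > 1L) {
    for (i in seq_along(drops)) for (j in seq_along(drops)) {
      if (j <= i) next
      di <- drops[[i]]; dj <- drops[[j]]
      if (sqrt((di$cx - dj$cx)^2 + (di$cy - dj$cy)^2) <= di$r + dj$r)
        stop("ambiguous ground truth: drops overlap", call. = FALSE)
    }
  }
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px), drops = drops,
                 red_rgb = as.integer(red_rgb),
                 medium_rgb = as.integer(medium_rgb),
                 bg_rgb = as.integer(bg_rgb), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "drop_scene_params")
}

#' Render a pigmented drop scene
#'
#' @param params a [drop_scene_params()] object.
#' @return list with `image` (H x W x 3 array, 8-bit values), `truth`
#'   (data frame: drop_id, cx, cy, r, n_interior, red_pixels,
#'   true_red_fraction), and `params`.
#' @export
render_drop_scene <- function(params) {
  stopifnot(inherits(params, "drop_scene_params"))
  p <- params
  withr::with_seed(p$seed, {
    H <- p$height_px; W <- p$width_px
    img <- array(0, dim = c(H, W, 3L))
    for (ch in 1:3) img[, , ch] <- p$bg_rgb[ch]
    xs <- col(matrix(0, H, W)) - 1L   # 0-based pixel centre coordinates
    ys <- row(matrix(0, H, W)) - 1L
    truth <- vector("list", length(p$drops))
    for (k in seq_along(p$drops)) {
      d <- p$drops[[k]]
      inside <- which((xs - d$cx)^2 + (ys - d$cy)^2 <= d$r^2)
      n_int <- length(inside)
      for (ch in 1:3) {
        plane <- img[, , ch]; plane[inside] <- p$medium_rgb[ch]
        img[, , ch] <- plane
      }
      n_red <- floor(d$red_fraction * n_int)
      if (n_red > 0L) {
        red_px <- sample(inside, n_red)
        for (ch in 1:3) {
          plane <- img[, , ch]; plane[red_px] <- p$red_rgb[ch]
          img[, , ch] <- plane
        }
      }
      truth[[k]] <- data.frame(drop_id = k, cx = d$cx, cy = d$cy, r = d$r,
                               n_interior = n_int, red_pixels = n_red,
                               true_red_fraction = n_red / n_int)
    }
    if (p$noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, p$noise_sd)
    list(image = quantize8(img), truth = do.call(rbind, truth), params = p)
  })
}

#' Polygon approximation of a circular drop boundary
#'
#' Returns a regular polygon inscribed in the circle, usable as a drop ROI
#' for [quantify_red_in_drops()].
#'
#' @param cx,cy centre (0-based pixel coordinates).
#' @param r radius in pixels.
#' @param n_vertices number of polygon vertices.
#' @return a [polygon_roi()].
#' @export
circle_polygon <- function(cx, cy, r, n_vertices = 72L) {
  th <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  polygon_roi(cbind(x = cx + r * cos(th), y = cy + r * sin(th)))
}
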