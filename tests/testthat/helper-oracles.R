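# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementation.

# occupancy scan over every grid cell
brute_box_count <- function(mask, s) {
  H <- nrow(mask); W <- ncol(mask)
  n <- 0L
  for (r0 in seq(1L, H, by = s)) {
    for (c0 in seq(1L, W, by = s)) {
      cell <- mask[r0:min(r0 + s - 1L, H), c0:min(c0 + s - 1L, W), drop = FALSE]
      if (any(cell)) n <- n + 1L
    }
  }
  n
}

# Huang fuzziness minimizer, direct scan over all candidate thresholds
brute_huang <- function(values) {
  h <- tabulate(as.integer(values) + 1L, nbins = 256L)
  occ <- which(h > 0L) - 1L
  gmin <- min(occ); gmax <- max(occ)
  C <- gmax - gmin
  best_t <- NA_integer_; best_S <- Inf
  for (t in gmin:(gmax - 1L)) {
    num0 <- den0 <- num1 <- den1 <- 0
    for (g in 0:255) {
      if (h[g + 1L] == 0L) next
      if (g <= t) { num0 <- num0 + h[g + 1L] * g; den0 <- den0 + h[g + 1L] }
      else { num1 <- num1 + h[g + 1L] * g; den1 <- den1 + h[g + 1L] }
    }
    m0 <- num0 / den0; m1 <- num1 / den1
    S <- 0
    for (g in 0:255) {
      if (h[g + 1L] == 0L) next
      m <- if (g <= t) m0 else m1
      mu <- 1 / (1 + abs(g - m) / C)
      if (mu < 1 - 1e-12)
        S <- S + h[g + 1L] * (-mu * log(mu) - (1 - mu) * log(1 - mu))
    }
    if (S < best_S) { best_S <- S; best_t <- t }
  }
  best_t
}

# even-odd point-in-polygon with boundary-inclusive rule, one point at a time
brute_point_in_polygon <- function(px, py, xv, yv) {
  n <- length(xv)
  inside <- FALSE
  for (e in seq_len(n)) {
    ax <- xv[e]; ay <- yv[e]
    bx <- xv[e %% n + 1L]; by <- yv[e %% n + 1L]
    cross <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
    if (abs(cross) < 1e-9 &&
        px >= min(ax, bx) - 1e-9 && px <= max(ax, bx) + 1e-9 &&
        py >= min(ay, by) - 1e-9 && py <= max(ay, by) + 1e-9)
      return(TRUE)
    if ((ay > py) != (by > py)) {
      xi <- ax + (py - ay) * (bx - ax) / (by - ay)
      if (px < xi) inside <- !inside
    }
  }
  inside
}

# shoelace polygon area
shoelace_area <- function(xv, yv) {
  n <- length(xv)
  s <- 0
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    s <- s + xv[i] * yv[j] - xv[j] * yv[i]
  }
  abs(s) / 2
}

# a row of well-separated circular drops with given red fractions
make_drop_scene <- function(fracs, seed, r = 45, spacing = 120,
                            noise_sd = 4) {
  n <- length(fracs)
  drops <- data.frame(cx = spacing / 2 + spacing * (seq_len(n) - 1),
                      cy = spacing / 2, r = r, red_fraction = fracs)
  p <- drop_scene_params(width_px = spacing * n, height_px = spacing,
                         drops = drops, noise_sd = noise_sd, seed = seed)
  scene <- render_drop_scene(p)
  scene$rois <- lapply(p$drops, function(d) circle_polygon(d$cx, d$cy, d$r))
  scene
}
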