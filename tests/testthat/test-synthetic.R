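test_that("deterministic straight growth traces a single horizontal ray", {
  p <- mycelium_params(n_tips0 = 1, branch_prob = 0, jitter_sd_rad = 0,
                       hypha_width_px = 1, noise_sd = 0, illum_amp = 0,
                       n_steps = 50, step_len_px = 4, seed = 1)
  sim <- simulate_mycelium(p)
  rows <- unique(which(sim$skeleton, arr.ind = TRUE)[, 1])
  expect_length(rows, 1L)
  cols <- which(sim$skeleton[rows, ])
  expect_equal(cols, seq(min(cols), max(cols)))  # contiguous ray
  expect_gte(max(cols), 50 * 4)                  # advanced the full length
})

test_that("noise-free rendering is exactly two-valued and seed-reproducible", {
  p <- mycelium_params(noise_sd = 0, illum_amp = 0, seed = 7)
  sim1 <- simulate_mycelium(p)
  expect_setequal(unique(as.vector(sim1$image)), c(30, 200))
  sim2 <- simulate_mycelium(p)
  expect_identical(sim1$image, sim2$image)
  expect_identical(sim1$skeleton, sim2$skeleton)
  # noisy images are reproducible too, and the generator leaves the
  # global RNG untouched
  pn <- mycelium_params(seed = 7)
  set.seed(123); before <- runif(1)
  a <- simulate_mycelium(pn)$image
  b <- simulate_mycelium(pn)$image
  expect_identical(a, b)
})

test_that("skeleton density grows with the branching probability", {
  mean_px <- vapply(c(0.01, 0.05, 0.15), function(bp) {
    mean(vapply(1:10, function(s)
      sum(simulate_mycelium(mycelium_params(branch_prob = bp, seed = s))$skeleton),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_px) > 0))
})

test_that("degenerate simulations are rejected", {
  expect_error(mycelium_params(n_steps = 0, seed = 1), "empty simulation")
  expect_error(mycelium_params(width_px = 32, seed = 1), "64")
  expect_error(mycelium_params(branch_prob = 1.5, seed = 1), "branch_prob")
  expect_error(mycelium_params(fg_level = 30, bg_level = 30, seed = 1))
  expect_error(mycelium_params(branch_prob = 0.1), "seed")
})

test_that("fractal fixtures have the exact advertised pixel sets", {
  sq <- render_fractal("filled_square", size_px = 81)
  expect_true(all(sq$mask)); expect_equal(dim(sq$mask), c(81, 81))
  expect_equal(sq$dimension, 2)

  ln <- render_fractal("line", size_px = 384)
  expect_equal(sum(ln$mask), 384)
  expect_length(unique(which(ln$mask, arr.ind = TRUE)[, 1]), 1L)
  expect_equal(ln$dimension, 1)

  ca <- render_fractal("sierpinski_carpet", level = 3)
  expect_equal(dim(ca$mask), c(27, 27))
  expect_equal(sum(ca$mask), 8^3)       # brute recursion: 8 copies per level
  expect_equal(ca$dimension, log(8) / log(3))
  expect_error(render_fractal("sierpinski_carpet", size_px = 26, level = 3),
               "3\\^level")

  du <- render_fractal("random_dust", size_px = 64, density = 0.1, seed = 5)
  expect_equal(sum(du$mask), floor(0.1 * 64^2))
  expect_identical(du$mask,
                   render_fractal("random_dust", size_px = 64, density = 0.1,
                                  seed = 5)$mask)
})

test_that("drop scenes paint the exact floored red pixel count", {
  d <- data.frame(cx = 60, cy = 60, r = 50, red_fraction = 0.5)
  p <- drop_scene_params(120, 120, d, noise_sd = 0, seed = 2)
  sc <- render_drop_scene(p)
  # brute force: count pixels equal to the red triple
  is_red <- sc$image[, , 1] == 180 & sc$image[, , 2] == 30 &
    sc$image[, , 3] == 40
  expect_equal(sum(is_red), sc$truth$red_pixels)
  expect_equal(sc$truth$red_pixels, floor(0.5 * sc$truth$n_interior))
  expect_equal(sc$truth$true_red_fraction,
               floor(0.5 * sc$truth$n_interior) / sc$truth$n_interior)

  # extremes: all-medium and all-red interiors
  p0 <- drop_scene_params(120, 120, transform(d, red_fraction = 0),
                          noise_sd = 0, seed = 2)
  sc0 <- render_drop_scene(p0)
  inter <- (col(sc0$image[, , 1]) - 1 - 60)^2 +
    (row(sc0$image[, , 1]) - 1 - 60)^2 <= 50^2
  expect_true(all(sc0$image[, , 1][inter] == 210))
  p1 <- drop_scene_params(120, 120, transform(d, red_fraction = 1),
                          noise_sd = 0, seed = 2)
  sc1 <- render_drop_scene(p1)
  expect_true(all(sc1$image[, , 1][inter] == 180))
})

test_that("invalid drop scenes are rejected", {
  two <- data.frame(cx = c(50, 110), cy = 60, r = 40,
                    red_fraction = 0.2)   # distance 60 < 2 * 40
  expect_error(drop_scene_params(200, 120, two, seed = 1), "overlap")
  off <- data.frame(cx = 10, cy = 60, r = 40, red_fraction = 0.2)
  expect_error(drop_scene_params(200, 120, off, seed = 1), "inside")
  bad <- data.frame(cx = 60, cy = 60, r = 40, red_fraction = 1.2)
  expect_error(drop_scene_params(200, 120, bad, seed = 1), "red_fraction")
})
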