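test_that("redundancy filter keeps the higher-priority spot of a close pair", {
  spots <- data.frame(x = c(10.0, 10.3), y = c(5, 5), z = c(2, 2),
                      n_inliers = c(40L, 35L), intensity = c(100, 200))
  out <- redundancy_filter(spots, 0.5)
  expect_identical(nrow(out), 1L)
  expect_identical(out$n_inliers, 40L)

  apart <- data.frame(x = c(10, 11), y = c(5, 5), z = c(2, 2),
                      n_inliers = c(40L, 35L), intensity = c(1, 1))
  expect_identical(nrow(redundancy_filter(apart, 0.5)), 2L)
  expect_identical(nrow(redundancy_filter(apart[0, ], 0.5)), 0L)
})

test_that("redundancy filter is idempotent and enforces the separation", {
  set.seed(8)
  spots <- data.frame(x = runif(200, 0, 20), y = runif(200, 0, 20),
                      z = runif(200, 0, 5),
                      n_inliers = sample(10:60, 200, TRUE),
                      intensity = runif(200, 10, 100))
  once <- redundancy_filter(spots, 0.75)
  P <- as.matrix(once[, c("x", "y", "z")])
  expect_gte(min(dist(P)), 0.75)
  twice <- redundancy_filter(once, 0.75)
  expect_identical(twice, once)
})

test_that("linear interpolation hits pixel values and midpoints", {
  x <- matrix(0, 8, 8); x[3, 4] <- 42; x[4, 4] <- 10
  img <- image_volume(x)
  expect_equal(measure_intensity(img, c(2, 3)), 42)
  x2 <- matrix(0, 8, 8); x2[3, 4] <- 0; x2[4, 4] <- 10
  expect_equal(measure_intensity(image_volume(x2), c(2.5, 3)), 5.0)
  expect_error(measure_intensity(img, c(-1, 3)), "bounds")
})

test_that("Gaussian refit recovers the rendered peak amplitude within 2%", {
  true <- c(10.3, 9.6, 10.2)
  A <- 800; B <- 50
  img <- image_volume(h_render_spot(c(21, 21, 21), true, rep(1.5, 3),
                                    amplitude = A, baseline = B))
  field <- h_spot_field(true, rep(1.5, 3), amplitude = A)
  cs <- ransac_single(field, params = ransac_params(rng_seed = 2))
  got <- measure_intensity(img, true, "gauss_refit",
                           inlier_positions =
                             field$positions[cs$inliers, , drop = FALSE],
                           sigma = 1.5)
  expect_lt(abs(got - (A + B)) / (A + B), 0.02)
})

test_that("mask filtering partitions detections by rounded position", {
  spots <- data.frame(x = c(10.4, 3.0, 7.6), y = c(10.4, 3.0, 2.2),
                      z = c(5.0, 1.0, 3.0), intensity = 1)
  ones <- image_volume(array(1, dim = c(16, 16, 8)))
  zeros <- image_volume(array(0, dim = c(16, 16, 8)))
  expect_identical(nrow(mask_filter(spots, ones)$inside), 3L)
  expect_identical(nrow(mask_filter(spots, zeros)$outside), 3L)

  m <- array(0, dim = c(16, 16, 8)); m[11, 11, 6] <- 1
  part <- mask_filter(spots[1, ], image_volume(m))
  expect_identical(nrow(part$inside), 1L)   # (10.4,10.4,5.0) -> (10,10,5)

  m2d <- matrix(0, 16, 16); m2d[11, 11] <- 1
  part2 <- mask_filter(spots, image_volume(m2d))   # 2D mask on 3D spots
  expect_identical(nrow(part2$inside), 1L)
})

test_that("anisotropy estimation fails cleanly on blank images", {
  blank <- image_volume(array(5, dim = c(32, 32, 16)))
  expect_error(estimate_anisotropy(blank, dog_params(1.5, 1.6, 10)),
               "anisotropy estimation failed")
})

test_that("anisotropy estimation recovers isotropy and 2x axial stretch", {
  iso <- simulate_scene(simulation_params(shape = c(128L, 128L, 32L),
                                          n_spots = 40L, rng_seed = 12L))
  a_iso <- estimate_anisotropy(iso$image, dog_params(1.5, 1.6, 20))
  expect_lt(abs(a_iso - 1.0), 0.05)

  st <- simulate_scene(simulation_params(shape = c(128L, 128L, 32L),
                                         n_spots = 40L, sigma_axial = 3.0,
                                         rng_seed = 13L))
  a_st <- estimate_anisotropy(st$image, dog_params(1.5, 1.6, 20))
  expect_lt(abs(a_st - 0.5), 0.05)
})

test_that("anisotropy estimation is invariant to intensity scaling", {
  sc <- simulate_scene(simulation_params(shape = c(96L, 96L, 24L),
                                         n_spots = 25L, rng_seed = 14L))
  a1 <- estimate_anisotropy(sc$image, dog_params(1.5, 1.6, 20))
  scaled <- image_volume(as.array(sc$image) * 3.7)
  a2 <- estimate_anisotropy(scaled, dog_params(1.5, 1.6, 3 * 20))
  expect_lt(abs(a1 - a2), 1e-3)
})
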