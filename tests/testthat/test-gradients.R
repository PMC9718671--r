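test_that("a radius-3 3D patch yields a 7x7x7 patch and 216 gradients", {
  img <- image_volume(array(runif(20^3), dim = c(20, 20, 20)))
  patch <- support_patch(img, c(10, 10, 10), 3L)
  expect_identical(dim(patch$values), c(7L, 7L, 7L))
  field <- compute_gradients(patch)
  expect_identical(field$n, 216L)
})

test_that("gradient count is (2r)^n for r in 1..5, n in 2..3", {
  img3 <- image_volume(array(runif(24^3), dim = c(24, 24, 24)))
  img2 <- image_volume(matrix(runif(24^2), 24, 24))
  for (r in 1:5) {
    expect_identical(compute_gradients(support_patch(img3, c(12, 12, 12), r))$n,
                     as.integer((2 * r)^3))
    expect_identical(compute_gradients(support_patch(img2, c(12, 12), r))$n,
                     as.integer((2 * r)^2))
  }
})

test_that("constant patches give zero gradients, ramps give the slope", {
  img <- image_volume(array(4.2, dim = c(12, 12, 12)))
  f0 <- compute_gradients(support_patch(img, c(6, 6, 6), 3L))
  expect_lt(max(abs(f0$vectors)), 1e-12)

  ramp <- image_volume(outer(outer(2 * (0:11), rep(1, 12)), rep(1, 12)))
  f1 <- compute_gradients(support_patch(ramp, c(6, 6, 6), 3L))
  expect_true(all(abs(f1$vectors[, 1] - 2) < 1e-12))
  expect_true(all(abs(f1$vectors[, 2:3]) < 1e-12))
})

test_that("gradient positions sit on the dual grid inside the patch", {
  img <- image_volume(array(runif(16^3), dim = c(16, 16, 16)))
  field <- compute_gradients(support_patch(img, c(8, 8, 8), 3L))
  expect_true(all(abs(field$positions %% 1 - 0.5) < 1e-12))
  expect_true(all(field$positions > 8 - 3 - 0.6 &
                  field$positions < 8 + 3 + 0.6))
})

test_that("symmetric patches have gradients summing to zero and DC invariance", {
  field <- h_spot_field(c(10, 10, 10), rep(1.5, 3))
  expect_lt(max(abs(colSums(field$vectors))), 1e-9)

  img <- image_volume(array(runif(14^3), dim = c(14, 14, 14)))
  p1 <- support_patch(img, c(7, 7, 7), 2L)
  p2 <- p1; p2$values <- p1$values + 123.4
  expect_equal(compute_gradients(p1)$vectors, compute_gradients(p2)$vectors,
               tolerance = 1e-12)
})

test_that("plane background subtraction recovers planes exactly", {
  img <- image_volume(array(runif(12^3), dim = c(12, 12, 12)))
  patch <- support_patch(img, c(6, 6, 6), 3L)
  expect_identical(subtract_background(patch, "none"), patch)

  ax <- 0:6
  plane <- outer(outer(3 + 2 * ax, rep(1, 7)), rep(1, 7)) -
    outer(outer(rep(1, 7), rep(0, 7)), ax, `+`)   # 3 + 2x - z
  pp <- patch; pp$values <- plane
  out <- subtract_background(pp, "plane")
  expect_lt(max(abs(out$values)), 1e-9)
})

test_that("plane subtraction leaves a spot's gradient field intact", {
  # a tight spot so its tails vanish on the patch boundary the plane fit uses
  spot <- h_render_spot(rep(7L, 3), c(3.3, 3.3, 3.3), rep(0.5, 3), 200)
  ax <- 0:6
  plane <- 10 + outer(outer(0.8 * ax, rep(1, 7)), rep(1, 7)) +
    outer(outer(rep(0, 7), 0.3 * ax), rep(1, 7), `+`)
  img <- image_volume(array(runif(12^3), dim = c(12, 12, 12)))
  p_spot <- support_patch(img, c(6, 6, 6), 3L); p_spot$values <- spot
  p_both <- p_spot; p_both$values <- spot + plane
  f_spot <- compute_gradients(p_spot)
  f_corr <- compute_gradients(subtract_background(p_both, "plane"))
  # away from the patch boundary the fields agree tightly
  interior <- rowSums(abs(sweep(f_corr$positions, 2L, c(3, 3, 3), `-`)) < 2) == 3L
  expect_lt(max(abs(f_corr$vectors[interior, ] - f_spot$vectors[interior, ])),
            1e-6)
})

test_that("degenerate patches are rejected", {
  patch <- structure(list(center = c(1L, 1L), radius = 0L,
                          values = matrix(1, 1, 1), ndim = 2L),
                     class = "support_patch")
  expect_error(compute_gradients(patch), "degenerate")
})
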