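test_that("point_line_distance matches closed form and a sampling oracle", {
  expect_equal(point_line_distance(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), 1.0)
  expect_equal(point_line_distance(c(2, 3, 4), c(0, 3, 4), c(1, 0, 0)), 0.0)
  expect_error(point_line_distance(c(0, 0), c(1, 1), c(0, 0)), "zero-length")
  expect_error(point_line_distance(c(0, 0), c(1, 1), c(2, 0)), "unit")

  set.seed(11)
  for (i in 1:20) {
    q <- rnorm(3); p <- rnorm(3)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    expect_equal(point_line_distance(q, p, u),
                 h_line_sample_distance(q, p, u), tolerance = 1e-6)
  }
})

test_that("fit_center solves exact 2D line intersections", {
  field <- gradient_field(rbind(c(0, 1), c(1, 0)),
                          rbind(c(0, -1), c(-1, 0)))
  fit <- fit_center(field, weights = "uniform")
  expect_equal(fit$center, c(0, 0), tolerance = 1e-12)
  expect_equal(fit$residuals, c(0, 0), tolerance = 1e-12)
  expect_identical(fit$used_count, 2L)
})

test_that("fit_center recovers a noise-free 3D Gaussian center to 1e-3", {
  # radius 4 so the patch covers the PSF core fully; the residual
  # finite-difference bias is then well below a millipixel
  true <- c(31.30, 30.50, 15.70)
  field <- h_spot_field(true, rep(1.5, 3), radius = 4L,
                        shape = c(64, 64, 32))
  fit <- fit_center(field)
  expect_true(all(abs(fit$center - true) < 1e-3))
})

test_that("anisotropy scaling recovers axially stretched spots", {
  true <- c(31.30, 30.50, 15.70)
  # radius 6 so the patch also covers two axial sigmas of the stretched PSF
  field <- h_spot_field(true, c(1.5, 1.5, 3.0), radius = 6L,
                        shape = c(64, 64, 32))
  fit_a <- fit_center(field, anisotropy_scale(0.5))
  fit_1 <- fit_center(field, anisotropy_scale(1.0))
  expect_true(all(abs(fit_a$center - true) < 1e-3))
  expect_gt(abs(fit_1$center[3] - true[3]), abs(fit_a$center[3] - true[3]))
})

test_that("pre-scaled fit equals anisotropy-corrected fit on raw data", {
  set.seed(21)
  field <- h_random_field(n = 12L)
  a <- 0.6
  fit_raw <- fit_center(field, anisotropy_scale(a), weights = "uniform")
  scaled <- gradient_field(sweep(field$positions, 2L, c(1, 1, a), `*`),
                           sweep(field$vectors, 2L, c(1, 1, a), `/`))
  fit_pre <- fit_center(scaled, anisotropy_scale(1), weights = "uniform")
  expect_equal(fit_pre$center / c(1, 1, a), fit_raw$center,
               tolerance = 1e-9)
})

test_that("fit_center matches a brute-force grid minimizer", {
  set.seed(31)
  for (i in 1:10) {
    field <- h_random_field(n = sample(4:12, 1))
    w <- field$magnitudes^2
    fit <- fit_center(field)
    grid <- h_grid_minimize(field, w, fit$center, span = 0.3, step = 0.03)
    expect_lt(sqrt(sum((grid$argmin - fit$center)^2)), 0.03 * sqrt(3))
    expect_lte(grid$objective(fit$center), grid$value + 1e-9)
  }
})

test_that("fit_center is translation and rotation equivariant", {
  set.seed(41)
  field <- h_random_field(n = 10L)
  fit0 <- fit_center(field, weights = "uniform")
  v <- c(2.5, -1.25, 4)
  fit_t <- fit_center(gradient_field(sweep(field$positions, 2L, v, `+`),
                                     field$vectors), weights = "uniform")
  expect_equal(fit_t$center, fit0$center + v, tolerance = 1e-9)

  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  fit_r <- fit_center(gradient_field(field$positions %*% t(R),
                                     field$vectors %*% t(R)),
                      weights = "uniform")
  expect_equal(fit_r$center, as.numeric(R %*% fit0$center),
               tolerance = 1e-9)
})

test_that("zero-weight gradients never influence the result", {
  set.seed(51)
  field <- h_random_field(n = 8L)
  junk <- gradient_field(rbind(field$positions, matrix(rnorm(9), 3, 3)),
                         rbind(field$vectors, matrix(rnorm(9, 5), 3, 3)))
  w <- c(rep(1, 8), rep(0, 3))
  expect_equal(fit_center(junk, weights = w)$center,
               fit_center(field, weights = rep(1, 8))$center,
               tolerance = 1e-12)
})

test_that("degenerate gradient sets are rejected", {
  par_field <- gradient_field(rbind(c(0, 0, 0), c(0, 1, 0)),
                              rbind(c(1, 0, 0), c(1, 0, 0)))
  expect_error(fit_center(par_field), "degenerate")
  single <- gradient_field(matrix(1:3, 1), matrix(1:3, 1))
  expect_error(fit_center(single), "insufficient")
})

test_that("minimal_center handles intersecting, skew and parallel lines", {
  f2 <- gradient_field(rbind(c(0, 1), c(1, 0)), rbind(c(0, -1), c(-1, 0)))
  expect_equal(minimal_center(f2), c(0, 0), tolerance = 1e-12)

  skew <- gradient_field(rbind(c(0, 0, 0), c(0, 1, 1)),
                         rbind(c(1, 0, 0), c(0, 1, 0)))
  got <- minimal_center(skew)
  grid <- h_grid_minimize(skew, c(1, 1), got, span = 0.5, step = 0.01)
  expect_lt(sqrt(sum((grid$argmin - got)^2)), 1e-4 + 0.01 * sqrt(3))
  # analytically: min over q of (y^2 + z^2) + (x^2 + (z - 1)^2)
  expect_equal(got, c(0, 0, 0.5), tolerance = 1e-9)

  same <- gradient_field(rbind(c(0, 0, 0), c(0, 0, 0)),
                         rbind(c(1, 0, 0), c(2, 0, 0)))
  expect_error(minimal_center(same), "degenerate")
})
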