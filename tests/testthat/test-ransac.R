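test_that("RANSAC on a clean spot agrees with the plain fit", {
  field <- h_spot_field(c(10.3, 9.6, 10.1), rep(1.5, 3))
  cs <- ransac_single(field, params = ransac_params(epsilon = 0.3,
                                                    rng_seed = 5))
  expect_false(is.null(cs))
  expect_gte(cs$n_inliers, 30L)
  plain <- fit_center(field)
  expect_lt(sqrt(sum((cs$center - plain$center)^2)), 0.05)
  expect_true(all(cs$residuals < 0.3))
})

test_that("RANSAC excludes injected hot-pixel outliers", {
  field <- h_spot_field(c(10.3, 9.6, 10.1), rep(1.5, 3))
  clean <- ransac_single(field, params = ransac_params(rng_seed = 5))
  poisoned <- field
  set.seed(99)
  bad <- sample(field$n, 20)
  poisoned$vectors[bad, ] <- matrix(rep(c(900, 100, -50), each = 20), 20)
  poisoned <- gradient_field(poisoned$positions, poisoned$vectors)
  cs <- ransac_single(poisoned, params = ransac_params(rng_seed = 5))
  expect_false(is.null(cs))
  expect_length(intersect(cs$inliers, bad), 0L)
  expect_lt(sqrt(sum((cs$center - clean$center)^2)), 0.1)
})

test_that("pure-noise fields are never accepted", {
  accepted <- 0L
  for (s in 1:100) {
    set.seed(s)
    field <- gradient_field(matrix(runif(216 * 3, 0, 7), 216, 3),
                            matrix(rnorm(216 * 3), 216, 3))
    cs <- ransac_single(field, params = ransac_params(min_inliers = 30L,
                                                      rng_seed = s))
    if (!is.null(cs)) accepted <- accepted + 1L
  }
  expect_identical(accepted, 0L)
})

test_that("RANSAC is deterministic given its seed", {
  field <- h_spot_field(c(10.4, 10.2, 9.8), rep(1.5, 3))
  field$vectors[1:40, ] <- field$vectors[1:40, ] +
    matrix(seq(-2, 2, length.out = 40), 40, 3)
  field <- gradient_field(field$positions, field$vectors)
  a <- ransac_single(field, params = ransac_params(rng_seed = 7))
  b <- ransac_single(field, params = ransac_params(rng_seed = 7))
  expect_identical(a$inliers, b$inliers)
  expect_identical(a$center, b$center)
})

test_that("multi-consensus separates two spots sharing one patch", {
  two <- h_render_spot(c(40, 40, 24), c(19, 20, 12), rep(1.5, 3), 1000) +
    h_render_spot(c(40, 40, 24), c(22, 20, 12), rep(1.5, 3), 1000)
  img <- image_volume(two)
  patch <- support_patch(img, c(20, 20, 12), 4L)
  field <- compute_gradients(patch)
  sets <- ransac_multi(field, params = ransac_params(rng_seed = 3))
  # the two dominant consensus sets recover the two spots; overlapping
  # tails can additionally support a small spurious midpoint consensus
  # (gradients of very close spots influence each other)
  expect_gte(length(sets), 2L)
  ord <- order(-vapply(sets, `[[`, integer(1), "n_inliers"))
  centers <- t(vapply(sets[ord[1:2]], `[[`, numeric(3), "center"))
  truth <- rbind(c(19, 20, 12), c(22, 20, 12))
  d <- apply(truth, 1, function(tt)
    min(sqrt(rowSums(sweep(centers, 2L, tt, `-`)^2))))
  expect_true(all(d < 0.5))
  for (i in seq_along(sets)[-1])
    expect_length(intersect(sets[[i - 1]]$inliers, sets[[i]]$inliers), 0L)
})

test_that("multi-consensus on a single clean spot yields exactly one set", {
  field <- h_spot_field(c(10.3, 9.6, 10.1), rep(1.5, 3))
  sets <- ransac_multi(field, params = ransac_params(rng_seed = 5))
  expect_identical(length(sets), 1L)
  single <- ransac_single(field, params = ransac_params(rng_seed = 5))
  expect_lt(sqrt(sum((sets[[1]]$center - single$center)^2)), 1e-6)
})

test_that("multi-consensus on an empty field returns an empty list", {
  field <- gradient_field(matrix(numeric(0), 0, 3),
                          matrix(numeric(0), 0, 3))
  expect_identical(ransac_multi(field), list())
})

test_that("accepted centers shift < 0.2 px under 30% outliers", {
  shifts <- numeric(0)
  for (s in 1:25) {
    field <- h_spot_field(c(10.3, 9.6, 10.1), rep(1.5, 3))
    clean <- ransac_single(field, params = ransac_params(rng_seed = s))
    set.seed(s)
    bad <- sample(field$n, round(0.3 * field$n))
    v <- field$vectors
    v[bad, ] <- matrix(rnorm(length(bad) * 3, 0, 200), length(bad), 3)
    noisy <- gradient_field(field$positions, v)
    cs <- ransac_single(noisy, params = ransac_params(rng_seed = s))
    expect_false(is.null(cs))
    shifts <- c(shifts, sqrt(sum((cs$center - clean$center)^2)))
  }
  expect_true(all(shifts < 0.2))
})
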