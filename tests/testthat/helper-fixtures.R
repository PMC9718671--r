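# Shared fixtures: analytic renderings and brute-force oracles, kept
# independent of the code paths they are used to check.

# Render one Gaussian spot into an array by direct evaluation at pixel
# centers (coordinates 0 .. shape-1), independent of the simulator.
h_render_spot <- function(shape, center, sigmas, amplitude = 1000,
                          baseline = 0) {
  ax <- lapply(seq_along(shape), function(d)
    exp(-((seq_len(shape[d]) - 1) - center[d])^2 / (2 * sigmas[d]^2)))
  baseline + amplitude * Reduce(`%o%`, ax)
}

# Gradient field of a rendered spot patch around an integer seed.
h_spot_field <- function(center, sigmas, radius = 3L, amplitude = 1000,
                         shape = NULL) {
  nd <- length(center)
  if (is.null(shape)) shape <- rep(2L * radius + 9L, nd)
  img <- image_volume(h_render_spot(shape, center, sigmas, amplitude))
  patch <- support_patch(img, round(center), radius)
  compute_gradients(patch)
}

# Brute-force point-to-line distance by dense sampling of the line.
h_line_sample_distance <- function(q, p, u, span = 50, n = 200001L) {
  t <- seq(-span, span, length.out = n)
  min(sqrt(colSums((outer(p, rep(1, n)) + outer(u, t) - q)^2)))
}

# Brute-force minimizer of sum w_k d_k^2 over a regular grid around x0.
h_grid_minimize <- function(field, weights, x0, span = 1, step = 0.02,
                            scale = anisotropy_scale()) {
  s <- rep(1, field$ndim)
  if (field$ndim >= 3L) s[3L] <- scale$factor
  p <- sweep(field$positions, 2L, s, `*`)
  g <- sweep(field$vectors, 2L, s, `/`)
  mag <- sqrt(rowSums(g^2))
  keep <- mag > 1e-12
  p <- p[keep, , drop = FALSE]
  u <- g[keep, , drop = FALSE] / mag[keep]
  w <- weights[keep]
  obj <- function(q) {
    d2 <- rowSums(sweep(p, 2L, q, `-`)^2) -
      rowSums(sweep(p, 2L, q, `-`) * u)^2
    sum(w * pmax(d2, 0))
  }
  ax <- lapply(seq_len(field$ndim),
               function(d) seq(x0[d] * s[d] - span, x0[d] * s[d] + span,
                               by = step))
  grid <- as.matrix(do.call(expand.grid, ax))
  # vectorized sum_k w_k d_k(q)^2 over all grid points at once
  qq <- rowSums(grid^2)
  QP <- grid %*% t(p)                         # G x K
  QU <- grid %*% t(u)
  pp <- rowSums(p^2); pu <- rowSums(p * u)
  D2 <- (outer(qq, pp, `+`) - 2 * QP) -
    (QU - matrix(pu, nrow(grid), length(pu), byrow = TRUE))^2
  vals <- pmax(D2, 0) %*% w
  best <- which.min(vals)
  list(argmin = grid[best, ] / s, value = vals[best], step = step,
       objective = obj)
}

# Random gradient field with lines passing near a common center.
h_random_field <- function(n = 10L, nd = 3L, center = rep(0, nd),
                           jitter = 0.1) {
  pos <- matrix(stats::runif(n * nd, -3, 3), n, nd)
  dirs <- sweep(pos, 2L, center + stats::rnorm(nd, 0, jitter), `-`)
  gradient_field(pos, -dirs * stats::runif(n, 0.5, 2))
}

# Small low-noise simulated scene used by several suites.
h_small_scene <- function(seed = 1L, n_spots = 10L, noise_sd = 5) {
  simulate_scene(simulation_params(shape = c(96L, 96L, 24L),
                                   n_spots = n_spots, noise_sd = noise_sd,
                                   rng_seed = seed))
}

h_test_config <- function(...) {
  args <- list(sigma = 1.5, threshold = 20, seed = 3L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(run_config, args)
}
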