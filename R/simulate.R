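# Ground-truth scene simulator: random sub-pixel spot positions, normally
# distributed brightnesses, Gaussian-PSF expected photon counts, Poisson
# shot noise, additive Gaussian read noise.  A pair mode places spot pairs
# at controlled separations to probe close-spot resolution.

#' Simulation parameters
#'
#' Defaults emulate a typical smFISH acquisition on the benchmark image
#' geometry: a 256 x 256 x 32 stack with 30 diffraction-limited spots of
#' ~1000 photons peak on a 100-photon background, lateral PSF sigma 1.5 px.
#'
#' @param shape image extents, `(x, y[, z])` (each >= 8)
#' @param n_spots number of spots (ignored in pair mode)
#' @param brightness_mean,brightness_sd normal distribution of spot peak
#'   brightness, in photons
#' @param sigma_lateral,sigma_axial Gaussian PSF extents in pixels
#' @param noise_sd standard deviation of the additive Gaussian read noise
#' @param baseline constant background offset, in photons
#' @param rng_seed integer seed; the whole scene is a deterministic
#'   function of the parameters and this seed
#' @param pair_separations optional numeric vector of pair distances in
#'   pixels; when set, the scene contains `pairs_per_separation` spot
#'   pairs at each separation instead of `n_spots` independent spots
#' @param pairs_per_separation pairs per separation value
#' @return a `simulation_params` list
#' @export
simulation_params <- function(shape = c(256L, 256L, 32L), n_spots = 30L,
                              brightness_mean = 1000, brightness_sd = 100,
                              sigma_lateral = 1.5, sigma_axial = 1.5,
                              noise_sd = 10, baseline = 100,
                              rng_seed = 42L,
                              pair_separations = NULL,
                              pairs_per_separation = 10L) {
  stopifnot(length(shape) %in% c(2L, 3L), all(shape >= 8L),
            n_spots >= 0L, sigma_lateral > 0, sigma_axial > 0,
            noise_sd >= 0, baseline >= 0)
  structure(list(shape = as.integer(shape), n_spots = as.integer(n_spots),
                 brightness_mean = brightness_mean,
                 brightness_sd = brightness_sd,
                 sigma_lateral = sigma_lateral, sigma_axial = sigma_axial,
                 noise_sd = noise_sd, baseline = baseline,
                 rng_seed = as.integer(rng_seed),
                 pair_separations = pair_separations,
                 pairs_per_separation = as.integer(pairs_per_separation)),
            class = "simulation_params")
}

.psf_sigmas <- function(params) {
  s <- rep(params$sigma_lateral, length(params$shape))
  if (length(params$shape) == 3L) s[3L] <- params$sigma_axial
  s
}

#' Render the noise-free expected image
#'
#' `I_pred = baseline + sum_spots brightness * exp(-sum_d (x_d - c_d)^2 /
#' (2 sigma_d^2))` evaluated at pixel centers; additive across spots.
#'
#' @param params a [simulation_params()]
#' @param truth `data.frame` with coordinate columns `x`, `y` (and `z`)
#'   and `brightness`
#' @return an `image_volume` with the expected photon count per pixel
#' @export
render_expected <- function(params, truth) {
  shape <- params$shape
  nd <- length(shape)
  sig <- .psf_sigmas(params)
  img <- array(params$baseline, dim = shape)
  cols <- c("x", "y", "z")[seq_len(nd)]
  win <- ceiling(5 * sig)             # beyond 5 sigma the PSF is ~1e-11
  for (i in seq_len(nrow(truth))) {
    ctr <- as.numeric(truth[i, cols])
    if (any(ctr < 0) || any(ctr > shape - 1L))
      stop("truth position outside image bounds")
    lo <- pmax(floor(ctr - win), 0)
    hi <- pmin(ceiling(ctr + win), shape - 1L)
    ax <- lapply(seq_len(nd), function(d) lo[d]:hi[d])
    g1 <- lapply(seq_len(nd), function(d)
      exp(-(ax[[d]] - ctr[d])^2 / (2 * sig[d]^2)))
    blob <- truth$brightness[i] * Reduce(`%o%`, g1)
    idx <- lapply(seq_len(nd), function(d) (lo[d]:hi[d]) + 1L)
    old <- do.call(`[`, c(list(img), idx, list(drop = FALSE)))
    img <- do.call(`[<-`, c(list(img), idx, list(old + blob)))
  }
  image_volume(img)
}

#' Simulate a ground-truth scene
#'
#' Spot positions are uniform over the volume (pair mode: anchors uniform
#' with partners at the requested separation in a uniformly random
#' direction, both kept in bounds); brightnesses are normal with a floor
#' of 1 photon; the recorded image is
#' `Poisson(I_pred) + Normal(0, noise_sd)`.  Deterministic given
#' `rng_seed`.
#'
#' @param params a [simulation_params()]
#' @return a `simulated_scene` list with `image` (an `image_volume`),
#'   `truth` (`data.frame` of positions and brightness) and `params`
#' @export
simulate_scene <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  .with_seed(params$rng_seed, {
    truth <- .draw_truth(params)
    expected <- render_expected(params, truth)
    noisy <- array(stats::rpois(length(expected$data),
                                lambda = as.vector(expected$data)),
                   dim = params$shape)
    if (params$noise_sd > 0)
      noisy <- noisy + array(stats::rnorm(length(noisy), 0, params$noise_sd),
                             dim = params$shape)
    structure(list(image = image_volume(noisy), truth = truth,
                   params = params),
              class = "simulated_scene")
  })
}

.draw_truth <- function(params) {
  shape <- params$shape
  nd <- length(shape)
  cols <- c("x", "y", "z")[seq_len(nd)]
  if (is.null(params$pair_separations)) {
    n <- params$n_spots
    pos <- vapply(seq_len(nd),
                  function(d) stats::runif(n, 0, shape[d] - 1L),
                  numeric(n))
    if (n == 1L) pos <- matrix(pos, 1L)
  } else {
    anchors <- list(); partners <- list()
    for (sep in params$pair_separations) {
      for (k in seq_len(params$pairs_per_separation)) {
        repeat {
          a <- vapply(seq_len(nd),
                      function(d) stats::runif(1L, 0, shape[d] - 1L),
                      numeric(1L))
          dir <- stats::rnorm(nd)
          dir <- dir / sqrt(sum(dir^2))
          b <- a + sep * dir
          if (all(b >= 0) && all(b <= shape - 1L)) break
        }
        anchors[[length(anchors) + 1L]] <- a
        partners[[length(partners) + 1L]] <- b
      }
    }
    pos <- rbind(do.call(rbind, anchors), do.call(rbind, partners))
    # interleave anchor/partner so pairs are adjacent rows
    np <- length(anchors)
    pos <- pos[as.vector(rbind(seq_len(np), np + seq_len(np))), ,
               drop = FALSE]
  }
  n <- nrow(pos)
  truth <- as.data.frame(pos)
  names(truth) <- cols
  truth$brightness <- pmax(1, stats::rnorm(n, params$brightness_mean,
                                           params$brightness_sd))
  truth
}
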