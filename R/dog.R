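# Difference-of-Gaussians seeding: candidate spots are strict local maxima
# of DoG(sigma, k*sigma) above an intensity threshold.

#' Difference-of-Gaussians parameters
#'
#' @param sigma lateral spot scale in pixels (> 0)
#' @param k ratio of the second Gaussian's sigma to the first (> 1);
#'   1.6 approximates the Laplacian of Gaussian
#' @param threshold minimum DoG response at a maximum (>= 0)
#' @param anisotropy axial scale factor `a`; the axial sigma is
#'   `sigma / a` so that axially elongated spots are seeded at the same
#'   scale as lateral ones (see [anisotropy_scale()])
#' @return a `dog_params` list
#' @export
dog_params <- function(sigma = 1.5, k = 1.6, threshold = 0.007,
                       anisotropy = 1.0) {
  stopifnot(sigma > 0, k > 1, threshold >= 0, anisotropy > 0)
  structure(list(sigma = sigma, k = k, threshold = threshold,
                 anisotropy = anisotropy), class = "dog_params")
}

# 1D normalized Gaussian kernel, radius ceiling(3 sigma)
.gauss_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# n x n convolution matrix with mirror boundary for a symmetric kernel
.conv_matrix <- function(kernel, n) {
  r <- (length(kernel) - 1L) %/% 2L
  if (r >= n)
    stop("Gaussian kernel (radius ", r, ") exceeds image extent ", n)
  K <- matrix(0, n, n)
  for (off in -r:r) {
    j <- .mirror_index(seq_len(n) + off, n)
    w <- kernel[off + r + 1L]
    K[cbind(seq_len(n), j)] <- K[cbind(seq_len(n), j)] + w
  }
  K
}

# Separable convolution of an n-D array along one axis (mirror boundary).
.convolve_axis <- function(x, kernel, axis) {
  d <- dim(x)
  nd <- length(d)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  xp <- aperm(x, perm)
  dm <- dim(xp)
  K <- .conv_matrix(kernel, dm[1L])
  y <- K %*% matrix(xp, nrow = dm[1L])
  dim(y) <- dm
  aperm(y, order(perm))
}

# Gaussian smoothing with per-axis sigmas.
.gauss_smooth <- function(x, sigmas) {
  for (axis in seq_along(sigmas))
    x <- .convolve_axis(x, .gauss_kernel(sigmas[axis]), axis)
  x
}

#' Difference-of-Gaussians filter
#'
#' Computes `G(sigma_vec) * image - G(k * sigma_vec) * image` with mirror
#' boundary extension, so bright spots give positive maxima and a constant
#' offset maps to zero response.  Per-axis sigmas are
#' `(sigma, sigma[, sigma / a])` with `a` the anisotropy factor.
#'
#' @param image an `image_volume` (in-memory)
#' @param params a [dog_params()] object
#' @return an `image_volume` holding the DoG response
#' @export
dog_filter <- function(image, params) {
  stopifnot(inherits(image, "image_volume"), inherits(params, "dog_params"))
  x <- as.array(image)
  sig <- rep(params$sigma, image$ndim)
  if (image$ndim == 3L) sig[3L] <- params$sigma / params$anisotropy
  resp <- .gauss_smooth(x, sig) - .gauss_smooth(x, params$k * sig)
  image_volume(resp)
}

#' Find seed points in a DoG response
#'
#' Seeds are strict local maxima over the full `3^n - 1` neighborhood
#' (plateau ties are not maxima) with response at or above `threshold`.
#' The neighborhood is mirror-extended at the image border — the same
#' boundary rule used by the filters and support patches — so spots close
#' to an edge keep their seed instead of silently disappearing.  Results
#' are sorted lexicographically by `(x, y[, z])`.
#'
#' @param dog an `image_volume` holding a DoG response
#' @param threshold minimum accepted response
#' @return `data.frame` with integer coordinate columns `x`, `y` (and `z`
#'   for 3D) in the package pixel-center convention, plus `dog_value`
#' @export
find_seeds <- function(dog, threshold) {
  stopifnot(inherits(dog, "image_volume"))
  D <- as.array(dog)
  d <- dim(D)
  nd <- length(d)
  ok <- D >= threshold
  offs <- as.matrix(expand.grid(rep(list(-1L:1L), nd)))
  offs <- offs[rowSums(offs != 0L) > 0L, , drop = FALSE]
  for (r in seq_len(nrow(offs))) {
    if (!any(ok)) break
    idx <- lapply(seq_len(nd), function(dd)
      .mirror_index(seq_len(d[dd]) + offs[r, dd], d[dd]))
    nb <- do.call(`[`, c(list(D), idx, list(drop = FALSE)))
    ok <- ok & (D > nb)
  }
  pos <- which(ok, arr.ind = TRUE)
  if (length(pos) == 0L)
    return(.seed_frame(matrix(integer(0), 0, nd), numeric(0), nd))
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = nd)
  vals <- D[pos]
  coords <- pos - 1L                  # 0-based pixel-center coordinates
  ord <- do.call(order, lapply(seq_len(nd), function(dd) coords[, dd]))
  .seed_frame(coords[ord, , drop = FALSE], vals[ord], nd)
}

#' Noise-adaptive DoG threshold
#'
#' Estimates the noise floor of a DoG response robustly (median absolute
#' deviation, which is insensitive to the sparse spot peaks) and returns
#' `n_sigma` times that scale, floored at `minimum`.  Useful for sweeping
#' noise levels with otherwise fixed detection parameters.
#'
#' @param dog an `image_volume` holding a DoG response
#' @param n_sigma multiple of the robust noise scale (default 5)
#' @param minimum lower bound for the returned threshold
#' @return a threshold value for [find_seeds()]
#' @export
auto_threshold <- function(dog, n_sigma = 5, minimum = 0) {
  stopifnot(inherits(dog, "image_volume"))
  max(minimum, n_sigma * stats::mad(as.vector(as.array(dog))))
}

.seed_frame <- function(coords, vals, nd) {
  df <- as.data.frame(coords)
  names(df) <- c("x", "y", "z")[seq_len(nd)]
  df$dog_value <- vals
  df
}
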