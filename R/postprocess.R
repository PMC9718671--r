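# Postprocessing of accepted centers: redundancy filtering, intensity
# measurement, binary-mask classification, and estimation of the global
# anisotropy factor from the image itself.

.pos_cols <- function(spots) intersect(c("x", "y", "z"), names(spots))

#' Remove redundant detections
#'
#' Greedily keeps spots so that all pairwise Euclidean distances are at
#' least `min_separation` (default 0.5 px).  Priority: higher `n_inliers`,
#' then higher `intensity`, then lexicographic position; a lower-priority
#' spot closer than `min_separation` to a kept one is dropped.
#'
#' @param spots `data.frame` with coordinate columns `x`, `y` (and `z`),
#'   optionally `n_inliers` and `intensity`
#' @param min_separation minimal allowed pairwise distance in pixels
#' @return the filtered `data.frame` (row order = kept priority order)
#' @export
redundancy_filter <- function(spots, min_separation = 0.5) {
  stopifnot(min_separation >= 0)
  spots <- as.data.frame(spots)
  n <- nrow(spots)
  if (n <= 1L || min_separation == 0) return(spots)
  cols <- .pos_cols(spots)
  P <- as.matrix(spots[, cols, drop = FALSE])
  ninl <- if (!is.null(spots$n_inliers)) spots$n_inliers else rep(0, n)
  inten <- if (!is.null(spots$intensity)) spots$intensity else rep(0, n)
  ord <- do.call(order, c(list(-ninl, -inten),
                          lapply(seq_along(cols), function(d) P[, d])))
  keep <- logical(n)
  kept <- matrix(numeric(0), 0, length(cols))
  for (i in ord) {
    if (nrow(kept) > 0L) {
      d2 <- rowSums(sweep(kept, 2L, P[i, ], `-`)^2)
      if (any(d2 < min_separation^2)) next
    }
    keep[i] <- TRUE
    kept <- rbind(kept, P[i, ])
  }
  spots[ord[keep[ord]], , drop = FALSE]
}

# n-linear interpolation of an in-memory volume at one sub-pixel position
# (0-based coordinates); clamped so positions on the far edge stay valid.
.interp_linear <- function(data, pos) {
  d <- dim(data)
  nd <- length(d)
  if (any(pos < 0) || any(pos > d - 1L)) stop("position outside image bounds")
  i0 <- pmin(floor(pos), d - 2L)
  i0 <- pmax(i0, 0)
  f <- pos - i0
  acc <- 0
  corners <- as.matrix(expand.grid(rep(list(0:1), nd)))
  for (r in seq_len(nrow(corners))) {
    cr <- corners[r, ]
    w <- prod(ifelse(cr == 1, f, 1 - f))
    if (w == 0) next
    acc <- acc + w * data[matrix(i0 + cr + 1L, 1L)]
  }
  acc
}

#' Measure a spot's intensity
#'
#' `mode = "interpolate"` returns the n-linear interpolation of the image
#' at the sub-pixel spot position.  `mode = "gauss_refit"` least-squares
#' fits amplitude `A` and offset `B` of a Gaussian with center fixed at
#' the spot position and per-axis sigma fixed at
#' `(sigma, sigma, sigma / a)`, over the pixels touched by the inlier
#' gradient cells, and returns `A + B` (the model value at the center); a
#' singular refit falls back to interpolation with a warning.
#'
#' @param image an `image_volume`
#' @param position sub-pixel spot position (0-based coordinates)
#' @param mode `"interpolate"` or `"gauss_refit"`
#' @param inlier_positions matrix of dual-grid positions of the inlier
#'   gradients (required for `gauss_refit`)
#' @param sigma lateral PSF sigma used by `gauss_refit`
#' @param anisotropy anisotropy factor `a` used by `gauss_refit`
#' @return the measured intensity
#' @export
measure_intensity <- function(image, position,
                              mode = c("interpolate", "gauss_refit"),
                              inlier_positions = NULL, sigma = 1.5,
                              anisotropy = 1.0) {
  mode <- match.arg(mode)
  stopifnot(inherits(image, "image_volume"),
            length(position) == image$ndim)
  d <- image$shape
  nd <- image$ndim
  if (mode == "interpolate") {
    if (any(position < 0) || any(position > d - 1L))
      stop("position outside image bounds")
    i0 <- pmax(pmin(floor(position), d - 2L), 0)
    box <- read_region(image, i0 + 1L, i0 + 2L)   # only the 2^n neighbors
    return(.interp_linear(box, position - i0))
  }
  if (is.null(inlier_positions))
    stop("gauss_refit requires the inlier gradient positions")
  # pixels touched by each dual-grid cell: the 2^n surrounding pixels
  base <- floor(inlier_positions)
  corners <- as.matrix(expand.grid(rep(list(0:1), nd)))
  px <- do.call(rbind, lapply(seq_len(nrow(corners)), function(r)
    sweep(base, 2L, corners[r, ], `+`)))
  px <- unique(px)
  ok <- rowSums(px < 0 | px >= matrix(d, nrow(px), nd, byrow = TRUE)) == 0L
  px <- px[ok, , drop = FALSE]
  blo <- apply(px, 2L, min); bhi <- apply(px, 2L, max)
  box <- read_region(image, blo + 1L, bhi + 1L)
  vals <- box[sweep(px, 2L, blo, `-`) + 1L]
  sig <- rep(sigma, nd)
  if (nd == 3L) sig[3L] <- sigma / anisotropy
  g <- exp(-rowSums(sweep(px, 2L, position, `-`)^2 /
                      matrix(2 * sig^2, nrow(px), nd, byrow = TRUE)))
  X <- cbind(g, 1)
  fit <- tryCatch(qr.coef(qr(X), vals), error = function(e) NULL)
  if (is.null(fit) || anyNA(fit) || stats::var(g) < 1e-12) {
    warning("singular Gaussian refit; falling back to interpolation")
    return(.interp_linear(data, position))
  }
  sum(fit)   # A + B = model value at the spot center
}

#' Classify spots with a binary mask
#'
#' A spot is inside iff the mask pixel at its rounded coordinates
#' (nearest integer, halves away from zero) is nonzero.  A 2D mask
#' applied to 3D detections classifies by `(x, y)` only.
#'
#' @param spots detection `data.frame` with `x`, `y` (and `z`) columns
#' @param mask an `image_volume` with nonzero = inside
#' @return list with elements `inside` and `outside`, a disjoint and
#'   exhaustive partition of `spots`
#' @export
mask_filter <- function(spots, mask) {
  stopifnot(inherits(mask, "image_volume"))
  spots <- as.data.frame(spots)
  cols <- .pos_cols(spots)
  nd_mask <- mask$ndim
  if (length(cols) < nd_mask)
    stop("mask has more dimensions than the detections")
  if (nrow(spots) == 0L)
    return(list(inside = spots, outside = spots))
  P <- as.matrix(spots[, cols[seq_len(nd_mask)], drop = FALSE])
  ridx <- .round_half_away(P)
  data <- as.array(mask)
  inb <- rowSums(ridx < 0 |
                 ridx >= matrix(mask$shape, nrow(ridx), nd_mask,
                                byrow = TRUE)) == 0L
  inside <- logical(nrow(spots))
  if (any(inb)) inside[inb] <- data[ridx[inb, , drop = FALSE] + 1L] != 0
  list(inside = spots[inside, , drop = FALSE],
       outside = spots[!inside, , drop = FALSE])
}

.round_half_away <- function(x) {
  s <- sign(x)
  s * floor(abs(x) + 0.5)
}

#' Estimate the global anisotropy factor from the image
#'
#' Detects DoG seeds (with `a = 1`), fits an axis-aligned elliptical
#' Gaussian (free per-axis sigmas, center, amplitude, offset) to the
#' patch around each of the brightest seeds, and returns the median over
#' spots of `mean(sigma_x, sigma_y) / sigma_z`.  The factor feeds
#' [anisotropy_scale()] and [dog_params()].
#'
#' @param image a 3D `image_volume` containing diffraction-limited spots
#' @param dog a [dog_params()] giving the seeding scale and threshold
#' @param n_spots_min minimal number of successful fits required
#' @param n_fit_max fit at most this many (brightest) seeds
#' @param fit_radius patch radius for the elliptical fit; default covers
#'   about four lateral sigmas
#' @return the estimated anisotropy factor `a`
#' @export
estimate_anisotropy <- function(image, dog, n_spots_min = 10L,
                                n_fit_max = 100L, fit_radius = NULL) {
  stopifnot(inherits(image, "image_volume"))
  if (image$ndim != 3L) stop("anisotropy estimation requires a 3D image")
  seed_dog <- dog_params(dog$sigma, dog$k, dog$threshold, anisotropy = 1.0)
  seeds <- find_seeds(dog_filter(image, seed_dog), seed_dog$threshold)
  if (nrow(seeds) == 0L)
    stop("anisotropy estimation failed: 0 spots (need >= ", n_spots_min, ")")
  seeds <- seeds[order(-seeds$dog_value), , drop = FALSE]
  seeds <- utils::head(seeds, n_fit_max)
  if (is.null(fit_radius))
    fit_radius <- max(5L, as.integer(ceiling(4 * dog$sigma)))
  ratios <- numeric(0)
  for (i in seq_len(nrow(seeds))) {
    ctr <- as.integer(seeds[i, c("x", "y", "z")])
    fit <- tryCatch(
      .fit_elliptical_gaussian(image, ctr, fit_radius),
      error = function(e) NULL)
    if (is.null(fit)) next
    sig <- fit$sigma
    if (any(sig < 0.2) || any(sig > 2 * fit_radius) || fit$A <= 0) next
    ratios <- c(ratios, mean(sig[1:2]) / sig[3L])
  }
  if (length(ratios) < n_spots_min)
    stop("anisotropy estimation failed: only ", length(ratios),
         " usable spots (need >= ", n_spots_min, ")")
  stats::median(ratios)
}

# Levenberg-Marquardt fit of A * exp(-sum (x - c)^2 / (2 s^2)) + B on the
# patch around an integer center.
.fit_elliptical_gaussian <- function(image, center, radius) {
  patch <- support_patch(image, center, radius)
  v <- as.vector(patch$values)
  nd <- patch$ndim
  ax <- lapply(seq_len(nd), function(d)
    center[d] - radius + (seq_len(2L * radius + 1L) - 1L))
  coords <- as.matrix(do.call(expand.grid, ax))
  B0 <- stats::median(v)
  A0 <- max(v) - B0
  par0 <- c(A = A0, B = B0, c = as.numeric(center), s = rep(1.5, nd))
  resid_fn <- function(par) {
    A <- par[1L]; B <- par[2L]
    cc <- par[3L:(2L + nd)]
    ss <- par[(3L + nd):(2L + 2L * nd)]
    model <- A * exp(-rowSums(sweep(coords, 2L, cc, `-`)^2 /
                                matrix(2 * ss^2, nrow(coords), nd,
                                       byrow = TRUE))) + B
    model - v
  }
  fit <- suppressWarnings(
    minpack.lm::nls.lm(par0, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 100L)))
  if (!fit$info %in% 1L:4L) stop("elliptical Gaussian fit did not converge")
  par <- fit$par
  list(A = par[[1L]], B = par[[2L]],
       center = as.numeric(par[3L:(2L + nd)]),
       sigma = abs(as.numeric(par[(3L + nd):(2L + 2L * nd)])))
}
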