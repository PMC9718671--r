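# Radial-symmetry localization: a spot center is the point minimizing the
# weighted sum of squared distances to the lines carried by the image
# gradients.  Axial anisotropy is handled without resampling the image by
# scaling positions with s = (1, 1, a) and gradients with s^-1.

#' Anisotropy scale
#'
#' The global anisotropy factor `a` maps an axially elongated PSF to
#' isotropy: positions are multiplied by `s = (1, 1, a)` and gradients by
#' `s^-1` before fitting, and the fitted center is mapped back.  With
#' `sigma_axial = sigma_lateral / a`, a PSF twice as long axially as
#' laterally corresponds to `a = 0.5`.  For 2D images the scale is the
#' identity.
#'
#' @param factor the anisotropy factor `a` (> 0); 1 means isotropic
#' @return an `anisotropy_scale` object
#' @export
anisotropy_scale <- function(factor = 1.0) {
  stopifnot(is.numeric(factor), length(factor) == 1L, factor > 0)
  structure(list(factor = factor), class = "anisotropy_scale")
}

.scale_vector <- function(scale, ndim) {
  s <- rep(1, ndim)
  if (ndim >= 3L) s[3L] <- scale$factor
  s
}

# Scale a gradient field into isotropic ("scaled") space.
.scale_field <- function(field, scale) {
  s <- .scale_vector(scale, field$ndim)
  gradient_field(sweep(field$positions, 2L, s, `*`),
                 sweep(field$vectors, 2L, s, `/`))
}

#' Distance from a point to a line
#'
#' The perpendicular distance from `q` to the line through `p` with unit
#' direction `u`: `sqrt(|q - p|^2 - ((q - p) . u)^2)`, clamped at 0
#' against rounding.
#'
#' @param q query point
#' @param p a point on the line
#' @param u unit direction vector (|u| = 1 within 1e-9)
#' @return nonnegative distance in pixels
#' @export
point_line_distance <- function(q, p, u) {
  nu <- sqrt(sum(u^2))
  if (nu < 1e-12) stop("zero-length line direction")
  if (abs(nu - 1) > 1e-9) stop("direction must be a unit vector")
  w <- q - p
  sqrt(max(0, sum(w^2) - sum(w * u)^2))
}

# Vectorized distances from one point to many lines (rows of p, unit rows u).
.point_lines_distance <- function(q, p, u) {
  w <- sweep(p, 2L, q, `-`)           # p - q; same squared norm as q - p
  proj <- rowSums(w * u)
  sqrt(pmax(0, rowSums(w^2) - proj^2))
}

#' Fit a spot center to a gradient field
#'
#' Solves the weighted normal equations
#' `[sum w_k (I - u_k u_k^T)] p = sum w_k (I - u_k u_k^T) p_k`
#' whose solution minimizes `sum w_k d_k^2`, the weighted squared
#' point-to-line distances.  Positions are scaled by `s` and gradients by
#' `s^-1` first; the center is mapped back to unscaled coordinates while
#' residuals are reported in scaled space.
#'
#' @param field a [gradient_field()]
#' @param scale an [anisotropy_scale()]
#' @param weights `"magnitude2"` (default; squared gradient magnitude after
#'   anisotropy scaling), `"magnitude"`, `"uniform"`, or a numeric vector
#'   of per-gradient nonnegative weights
#' @return a `center_fit` with fields `center` (unscaled coordinates),
#'   `residuals` (scaled space, for the gradients used), `used` (indices
#'   of gradients used) and `used_count`
#' @export
fit_center <- function(field, scale = anisotropy_scale(),
                       weights = "magnitude2") {
  sf <- .scale_field(field, scale)
  w <- .resolve_weights(sf, weights)
  keep <- which(sf$magnitudes > 1e-12 & w > 0)
  if (length(keep) < 2L)
    stop("insufficient data: need >= 2 usable gradients")
  p <- sf$positions[keep, , drop = FALSE]
  u <- sf$vectors[keep, , drop = FALSE] / sf$magnitudes[keep]
  wk <- w[keep]
  nd <- field$ndim
  # A = sum w (I - u u^T) = sum(w) I - U^T diag(w) U ; b likewise
  A <- sum(wk) * diag(nd) - crossprod(u * sqrt(wk))
  proj <- rowSums(p * u)
  b <- colSums(p * wk) - colSums(u * (wk * proj))
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(ev))
    stop("degenerate fit: gradient directions are (near) parallel")
  centre_scaled <- solve(A, b)
  res <- .point_lines_distance(centre_scaled, p, u)
  s <- .scale_vector(scale, nd)
  structure(list(center = as.numeric(centre_scaled / s),
                 residuals = res, used = keep,
                 used_count = length(keep)),
            class = "center_fit")
}

.resolve_weights <- function(field, weights) {
  if (is.character(weights)) {
    weights <- match.arg(weights, c("magnitude2", "magnitude", "uniform"))
    return(switch(weights,
                  magnitude2 = field$magnitudes^2,
                  magnitude = field$magnitudes,
                  uniform = rep(1, field$n)))
  }
  stopifnot(length(weights) == field$n, all(weights >= 0))
  as.numeric(weights)
}

#' Center from the minimal two-gradient sample
#'
#' Equivalent to [fit_center()] restricted to two gradients with unit
#' weights: the midpoint of mutual closest approach of the two lines in
#' scaled space, mapped back to unscaled coordinates.
#'
#' @param field a [gradient_field()] with exactly two gradients (or
#'   `indices` selecting two)
#' @param scale an [anisotropy_scale()]
#' @param indices optional pair of row indices into `field`
#' @return numeric center point (unscaled coordinates)
#' @export
minimal_center <- function(field, scale = anisotropy_scale(),
                           indices = NULL) {
  if (!is.null(indices)) {
    stopifnot(length(indices) == 2L)
    field <- gradient_field(field$positions[indices, , drop = FALSE],
                            field$vectors[indices, , drop = FALSE])
  }
  stopifnot(field$n == 2L)
  fit_center(field, scale, weights = "uniform")$center
}
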