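# RANSAC on gradient lines: find the largest subset of gradients whose
# lines pass within epsilon of a common center, then refit on the inliers.
# Multi-consensus mode repeats on the surviving gradients to pull apart
# spots that share one DoG seed.

#' RANSAC parameters
#'
#' @param epsilon maximal point-to-line distance for an inlier, in pixels
#'   of the anisotropy-scaled space (> 0)
#' @param min_inliers minimal consensus size to accept a spot (>= 2;
#'   around 30 is typical for a radius-3 3D patch)
#' @param max_iterations cap on sampling rounds
#' @param confidence target probability of having drawn at least one
#'   all-inlier pair; drives the adaptive iteration bound
#' @param multi_consensus run repeated consensus extraction ([ransac_multi()])
#' @param rng_seed integer seed making the sampling deterministic
#' @return a `ransac_params` list
#' @export
ransac_params <- function(epsilon = 0.5, min_inliers = 30L,
                          max_iterations = 1000L, confidence = 0.99,
                          multi_consensus = FALSE, rng_seed = 42L) {
  stopifnot(epsilon > 0, min_inliers >= 2L, max_iterations >= 1L,
            confidence > 0, confidence < 1)
  structure(list(epsilon = epsilon, min_inliers = as.integer(min_inliers),
                 max_iterations = as.integer(max_iterations),
                 confidence = confidence,
                 multi_consensus = isTRUE(multi_consensus),
                 rng_seed = as.integer(rng_seed)),
            class = "ransac_params")
}

# Evaluate expr under a temporary, seeded RNG; the caller's RNG state is
# untouched.  All stochastic steps in this package go through this helper.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

# Stable per-candidate seed from the global seed and an integer position,
# independent of block layout or traversal order.  Horner scheme mod a
# prime < 2^31 keeps everything exact in doubles.
.derive_seed <- function(global_seed, position) {
  M <- 2147483629
  h <- (as.numeric(global_seed) %% M + 7) %% M
  for (v in c(as.numeric(position), length(position)))
    h <- (h * 1159 + (v %% M) + 3) %% M
  as.integer(h %% 2147483587 + 1)
}

#' Single-consensus RANSAC spot fit
#'
#' Repeatedly samples two gradients, computes their minimal center, and
#' counts gradients whose lines pass within `epsilon`; the largest
#' consensus (ties broken by smaller mean residual) is refit with
#' [fit_center()] on all its inliers, inliers are re-selected once against
#' the refit center, and the final center is refit on those.  Returns
#' `NULL` when the best consensus is smaller than `min_inliers`.
#'
#' @param field a [gradient_field()]
#' @param scale an [anisotropy_scale()]
#' @param params a [ransac_params()]
#' @param weights weighting scheme passed to [fit_center()]
#' @param candidates optional subset of gradient indices to consider
#' @return a `consensus_set` (fields `inliers`, `center`, `residuals`,
#'   `mean_residual`) or `NULL`
#' @export
ransac_single <- function(field, scale = anisotropy_scale(),
                          params = ransac_params(),
                          weights = "magnitude2", candidates = NULL) {
  stopifnot(inherits(field, "gradient_field"))
  if (is.null(candidates)) candidates <- seq_len(field$n)
  .with_seed(params$rng_seed,
             .ransac_single_impl(field, scale, params, weights, candidates))
}

.ransac_single_impl <- function(field, scale, params, weights, candidates) {
  sf <- .scale_field(field, scale)
  usable <- candidates[sf$magnitudes[candidates] > 1e-12]
  m <- length(usable)
  if (m < max(2L, params$min_inliers)) return(NULL)
  p <- sf$positions[usable, , drop = FALSE]
  u <- sf$vectors[usable, , drop = FALSE] / sf$magnitudes[usable]
  best_count <- 0L
  best_mean <- Inf
  best_in <- integer(0)
  n_iter <- params$max_iterations
  it <- 0L
  while (it < n_iter) {
    it <- it + 1L
    pair <- sample.int(m, 2L)
    c_try <- tryCatch(
      .two_line_center(p[pair, ], u[pair, ]),
      error = function(e) NULL)
    if (is.null(c_try)) next
    d <- .point_lines_distance(c_try, p, u)
    inl <- d < params$epsilon
    cnt <- sum(inl)
    if (cnt > best_count ||
        (cnt == best_count && cnt > 0L && mean(d[inl]) < best_mean)) {
      best_count <- cnt
      best_mean <- if (cnt > 0L) mean(d[inl]) else Inf
      best_in <- which(inl)
      if (cnt > 2L) {      # adaptive standard RANSAC bound
        w_frac <- cnt / m
        n_ad <- ceiling(log(1 - params$confidence) /
                          log(1 - w_frac^2))
        n_iter <- min(params$max_iterations, max(it, n_ad))
      }
    }
  }
  if (best_count < params$min_inliers) return(NULL)
  refit1 <- tryCatch(
    .fit_subset(field, scale, weights, usable[best_in]),
    error = function(e) NULL)
  if (is.null(refit1)) return(NULL)
  s <- .scale_vector(scale, field$ndim)
  d1 <- .point_lines_distance(refit1$center * s, p, u)
  resel <- which(d1 < params$epsilon)
  if (length(resel) < params$min_inliers) return(NULL)
  refit2 <- tryCatch(
    .fit_subset(field, scale, weights, usable[resel]),
    error = function(e) NULL)
  if (is.null(refit2)) return(NULL)
  d2 <- .point_lines_distance(refit2$center * s, p, u)
  final <- which(d2 < params$epsilon)
  final <- intersect(resel, final)
  if (length(final) < params$min_inliers) return(NULL)
  inliers <- usable[final]
  structure(list(inliers = inliers, center = refit2$center,
                 residuals = d2[final], mean_residual = mean(d2[final]),
                 n_inliers = length(inliers)),
            class = "consensus_set")
}

# Least-squares meeting point of two lines given as rows of p (points) and
# u (unit directions), identical to the two-gradient normal equations.
.two_line_center <- function(p, u) {
  nd <- ncol(p)
  A <- 2 * diag(nd) - crossprod(u)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(ev)) stop("degenerate fit: parallel lines")
  b <- colSums(p) - colSums(u * rowSums(p * u))
  solve(A, b)
}

# fit_center on a subset of gradient indices, preserving weighting mode.
.fit_subset <- function(field, scale, weights, idx) {
  sub <- gradient_field(field$positions[idx, , drop = FALSE],
                        field$vectors[idx, , drop = FALSE])
  w <- if (is.character(weights)) weights else weights[idx]
  fit_center(sub, scale, w)
}

#' Multi-consensus RANSAC
#'
#' Runs [ransac_single()] repeatedly on the same candidate gradients,
#' removing each accepted consensus from the pool, until no further
#' consensus reaches `min_inliers`.  Close spots merged into one DoG seed
#' are thereby split into separate detections.
#'
#' @inheritParams ransac_single
#' @return list of `consensus_set` objects, in acceptance order (possibly
#'   empty)
#' @export
ransac_multi <- function(field, scale = anisotropy_scale(),
                         params = ransac_params(),
                         weights = "magnitude2") {
  stopifnot(inherits(field, "gradient_field"))
  out <- list()
  pool <- seq_len(field$n)
  round <- 0L
  while (length(pool) >= params$min_inliers) {
    round_params <- params
    round_params$rng_seed <- .derive_seed(params$rng_seed, round)
    cs <- ransac_single(field, scale, round_params, weights,
                        candidates = pool)
    if (is.null(cs)) break
    out[[length(out) + 1L]] <- cs
    pool <- setdiff(pool, cs$inliers)
    round <- round + 1L
  }
  out
}
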