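# Local gradient fields: finite-difference gradients on the dual
# (inter-pixel) grid of a support patch around a seed.  A radius-r patch
# has side 2r+1 and yields (2r)^n gradients — 216 for r = 3 in 3D.

#' Extract the support patch around a seed
#'
#' Reads the `(2r+1)^n` intensity patch centered on an integer seed
#' position, mirror-extending the image at its borders.
#'
#' @param image an `image_volume`
#' @param center integer seed coordinates (0-based pixel-center convention)
#' @param radius support region radius r in pixels (>= 1)
#' @return a `support_patch` with fields `center`, `radius`, `values`
#' @export
support_patch <- function(image, center, radius = 3L) {
  stopifnot(inherits(image, "image_volume"), length(center) == image$ndim,
            radius >= 1L)
  center <- as.integer(round(center))
  lo <- center + 1L - radius          # to 1-based array indices
  hi <- center + 1L + radius
  vals <- .read_region_mirrored(image, lo, hi)
  # flag fabricated pixels (mirror padding outside the true image): they
  # duplicate interior data and must not drive a localization fit
  mir_ax <- lapply(seq_len(image$ndim), function(d) {
    idx <- lo[d]:hi[d]
    idx < 1L | idx > image$shape[d]
  })
  mirrored <- Reduce(`|`, lapply(seq_len(image$ndim), function(d) {
    m <- array(FALSE, dim = dim(vals))
    perm <- c(d, setdiff(seq_len(image$ndim), d))
    aperm(array(mir_ax[[d]], dim = dim(vals)[perm]), order(perm))
  }))
  structure(list(center = center, radius = as.integer(radius),
                 values = vals, mirrored = mirrored, ndim = image$ndim),
            class = "support_patch")
}

#' Subtract a background estimate from a support patch
#'
#' `mode = "none"` returns the patch unchanged.  `mode = "plane"` fits an
#' affine function by least squares to the patch's boundary pixels only —
#' so a centered spot does not bias the estimate — and subtracts it from
#' every pixel.  Useful for non-uniform fluorescence backgrounds.
#'
#' @param patch a [support_patch()]
#' @param mode `"none"` or `"plane"`
#' @return a `support_patch` with adjusted values
#' @export
subtract_background <- function(patch, mode = c("none", "plane")) {
  mode <- match.arg(mode)
  if (mode == "none") return(patch)
  v <- patch$values
  d <- dim(v)
  nd <- patch$ndim
  ax <- lapply(d, function(n) seq_len(n) - 1)
  coords <- as.matrix(do.call(expand.grid, ax))
  on_boundary <- rowSums(coords == 0 |
                         coords == matrix(d - 1L, nrow(coords), nd,
                                          byrow = TRUE)) > 0L
  X <- cbind(1, coords)
  beta <- stats::lsfit(coords[on_boundary, , drop = FALSE],
                       as.vector(v)[on_boundary], intercept = TRUE)$coefficients
  bg <- X %*% beta
  patch$values <- v - array(bg, dim = d)
  patch
}

#' Compute the gradient field of a support patch
#'
#' For every cell of `2^n` adjacent pixels, one gradient vector is placed
#' at the cell center (half-integer dual-grid coordinates).  The component
#' along axis d is the separable convolution of the difference kernel
#' `(+1, -1)` along d with the averaging kernel `(1/2, 1/2)` along every
#' other axis, so for a bright spot gradients point toward its center.
#'
#' @param patch a [support_patch()] (side >= 2 per axis)
#' @return a `gradient_field` with matrix fields `positions` (global
#'   dual-grid coordinates) and `vectors`, plus `magnitudes`
#' @export
compute_gradients <- function(patch) {
  v <- patch$values
  d <- dim(v)
  nd <- patch$ndim
  if (any(d < 2L)) stop("degenerate patch: side < 2")
  diff_axis <- function(x, axis) {
    n <- dim(x)[axis]
    i1 <- lapply(dim(x), seq_len); i0 <- i1
    i1[[axis]] <- 2L:n; i0[[axis]] <- 1L:(n - 1L)
    do.call(`[`, c(list(x), i1, list(drop = FALSE))) -
      do.call(`[`, c(list(x), i0, list(drop = FALSE)))
  }
  avg_axis <- function(x, axis) {
    n <- dim(x)[axis]
    i1 <- lapply(dim(x), seq_len); i0 <- i1
    i1[[axis]] <- 2L:n; i0[[axis]] <- 1L:(n - 1L)
    (do.call(`[`, c(list(x), i1, list(drop = FALSE))) +
       do.call(`[`, c(list(x), i0, list(drop = FALSE)))) / 2
  }
  comps <- lapply(seq_len(nd), function(axis) {
    g <- diff_axis(v, axis)
    for (other in setdiff(seq_len(nd), axis)) g <- avg_axis(g, other)
    as.vector(g)
  })
  vectors <- do.call(cbind, comps)
  cell0 <- lapply(seq_len(nd), function(axis) {
    patch$center[axis] - patch$radius + (seq_len(d[axis] - 1L) - 1L) + 0.5
  })
  positions <- as.matrix(do.call(expand.grid, cell0))
  colnames(positions) <- colnames(vectors) <- c("x", "y", "z")[seq_len(nd)]
  fab <- NULL
  if (!is.null(patch$mirrored) && any(patch$mirrored)) {
    # a gradient is fabricated if any pixel of its 2^n cell is mirrored
    f <- patch$mirrored
    max_axis <- function(x, axis) {
      n <- dim(x)[axis]
      i1 <- lapply(dim(x), seq_len); i0 <- i1
      i1[[axis]] <- 2L:n; i0[[axis]] <- 1L:(n - 1L)
      do.call(`[`, c(list(x), i1, list(drop = FALSE))) |
        do.call(`[`, c(list(x), i0, list(drop = FALSE)))
    }
    for (axis in seq_len(nd)) f <- max_axis(f, axis)
    fab <- as.vector(f)
  }
  gradient_field(positions, vectors, fabricated = fab)
}

#' Construct a gradient field
#'
#' @param positions numeric matrix of gradient base points (rows = gradients)
#' @param vectors numeric matrix of gradient vectors, same shape
#' @param fabricated optional logical vector marking gradients whose cell
#'   touches mirror-padded pixels; such gradients describe fabricated data
#'   and are excluded from localization fits
#' @return a `gradient_field` list with `positions`, `vectors`,
#'   `magnitudes`, `fabricated`, `n` and `ndim`
#' @export
gradient_field <- function(positions, vectors, fabricated = NULL) {
  positions <- as.matrix(positions); vectors <- as.matrix(vectors)
  stopifnot(all(dim(positions) == dim(vectors)))
  if (is.null(fabricated)) fabricated <- rep(FALSE, nrow(positions))
  stopifnot(length(fabricated) == nrow(positions))
  structure(list(positions = positions, vectors = vectors,
                 magnitudes = sqrt(rowSums(vectors^2)),
                 fabricated = fabricated,
                 n = nrow(positions), ndim = ncol(positions)),
            class = "gradient_field")
}

# Subset a gradient field by row indices.
.field_subset <- function(field, idx) {
  gradient_field(field$positions[idx, , drop = FALSE],
                 field$vectors[idx, , drop = FALSE],
                 field$fabricated[idx])
}

#' @export
print.gradient_field <- function(x, ...) {
  cat(sprintf("<gradient_field> %d gradients in %dD\n", x$n, x$ndim))
  invisible(x)
}
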