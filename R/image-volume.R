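# Coordinate convention used by every module in this package:
# pixel centers sit at integer coordinates, the first pixel of the first
# row/slice is at (0.0, 0.0[, 0.0]).  R arrays are 1-based, so array index
# i corresponds to coordinate i - 1.  This is the single shared constant;
# no module applies any additional half-pixel shift.
.COORD_ORIGIN <- 0

#' Create an in-memory image volume
#'
#' An `image_volume` is a 2D or 3D scalar intensity grid with a fixed
#' internal axis order `(x, y[, z])` — x is the fastest-varying array
#' dimension — and an optional per-axis physical pixel spacing.  Pixel
#' centers sit at integer coordinates starting at 0 along every axis.
#'
#' @param data numeric matrix (2D) or 3D array, axis order `(x, y[, z])`.
#'   All values must be finite.
#' @param spacing optional numeric per-axis physical pixel size (e.g.
#'   micrometers per pixel), same length as `dim(data)`.
#' @return an object of class `image_volume` with fields `data`, `shape`,
#'   `ndim`, `axes` and `spacing`.
#' @examples
#' v <- image_volume(array(runif(8 * 8 * 4), dim = c(8, 8, 4)))
#' v$shape
#' @export
image_volume <- function(data, spacing = NULL) {
  if (is.null(dim(data))) stop("data must be a matrix or array")
  nd <- length(dim(data))
  if (nd < 2L || nd > 3L)
    stop("unsupported dimensionality: ", nd, " (must be 2 or 3)")
  if (any(dim(data) < 1L)) stop("all extents must be >= 1")
  if (!all(is.finite(data))) stop("image intensities must be finite")
  if (!is.null(spacing)) {
    stopifnot(length(spacing) == nd, all(spacing > 0))
  }
  structure(
    list(data = data, shape = dim(data), ndim = nd,
         axes = c("x", "y", "z")[seq_len(nd)], spacing = spacing,
         backend = NULL),
    class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s [%s]%s\n",
              paste(x$shape, collapse = " x "),
              paste(x$axes, collapse = ","),
              if (is.null(x$backend)) "" else " (lazy chunked)"))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) x$shape

#' Materialize an image volume as a plain array
#' @param x an `image_volume`
#' @param ... unused
#' @return numeric array with dimensions `x$shape`
#' @export
as.array.image_volume <- function(x, ...) {
  if (is.null(x$backend)) x$data
  else read_region(x, rep(1L, x$ndim), x$shape)
}

#' Read a rectangular region of an image volume
#'
#' Works for in-memory and lazy (chunked-store) volumes alike; only the
#' chunks overlapping the request are read from disk.  Indices are 1-based
#' and inclusive, in the internal `(x, y[, z])` axis order.
#'
#' @param vol an `image_volume`
#' @param lo,hi integer per-axis index bounds, `1 <= lo <= hi <= shape`
#' @return numeric array of dimensions `hi - lo + 1`
#' @export
read_region <- function(vol, lo, hi) {
  stopifnot(inherits(vol, "image_volume"),
            length(lo) == vol$ndim, length(hi) == vol$ndim)
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (any(lo < 1L) || any(hi > vol$shape) || any(lo > hi))
    stop("region out of bounds")
  if (is.null(vol$backend)) {
    idx <- lapply(seq_len(vol$ndim), function(d) lo[d]:hi[d])
    return(do.call(`[`, c(list(vol$data), idx, list(drop = FALSE))))
  }
  .read_region_chunked(vol, lo, hi)
}

# --- TIFF -------------------------------------------------------------------

# TIFF pages are stored [row, col] = [y, x]; internal order is (x, y, z),
# so each page is transposed on load and save.
.tiff_page_to_xy <- function(m) {
  if (length(dim(m)) == 3L) m <- m[, , 1L]   # collapse grayscale channel dim
  t(m)
}

#' Read an image from disk
#'
#' Reads either a (multi-page) TIFF file, where pages are stacked along z,
#' or a dataset inside a chunked store directory written by
#' [write_image()].  TIFF pixel values are returned as stored (integer
#' counts for integer TIFFs).
#'
#' @param path file (TIFF) or store directory (chunked)
#' @param dataset dataset name inside a chunked store; ignored for TIFF
#' @param lazy for chunked stores, return a lazy volume whose chunks are
#'   read on demand via [read_region()]
#' @return an `image_volume`
#' @export
read_image <- function(path, dataset = NULL, lazy = FALSE) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (dir.exists(path)) return(.read_chunked(path, dataset, lazy = lazy))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  planes <- lapply(pages, .tiff_page_to_xy)
  d <- dim(planes[[1L]])
  if (length(pages) == 1L) {
    data <- planes[[1L]]
  } else {
    data <- array(0, dim = c(d, length(planes)))
    for (k in seq_along(planes)) data[, , k] <- planes[[k]]
  }
  if (!all(is.finite(data))) stop("image contains non-finite values")
  image_volume(data)
}

#' Write an image to disk
#'
#' TIFF output (`path` ending in `.tif`/`.tiff`) stores integer counts —
#' values must be integer-valued in `[0, 65535]` (16-bit) as produced by a
#' camera or by [simulate_scene()]; use a chunked store for arbitrary
#' float data.  A chunked store (`path` is a directory, plus `dataset`)
#' stores exact float64 values in per-chunk raw files with a JSON
#' attributes sidecar, and can be read lazily block by block.
#'
#' @param vol an `image_volume` (in-memory)
#' @param path output TIFF file or store directory
#' @param dataset dataset name for chunked stores
#' @param chunks per-axis chunk sizes for chunked stores
#'   (default `c(64, 64, 32)` truncated to the image rank)
#' @return `path`, invisibly
#' @export
write_image <- function(vol, path, dataset = NULL,
                        chunks = c(64L, 64L, 32L)) {
  stopifnot(inherits(vol, "image_volume"), is.null(vol$backend))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    x <- vol$data
    if (any(x < 0) || any(x > 65535) || any(x != round(x)))
      stop("TIFF output requires integer values in [0, 65535]; ",
           "use a chunked store for float data")
    pages <- if (vol$ndim == 2L) list(t(x))
             else lapply(seq_len(vol$shape[3L]), function(k) t(x[, , k]))
    pages <- lapply(pages, function(p) p / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
    return(invisible(path))
  }
  .write_chunked(vol, path, dataset, chunks)
}

# --- minimal chunked store --------------------------------------------------
# Layout (one directory per dataset, in the spirit of N5/Zarr):
#   <path>/<dataset>/attributes.json   {"dimensions", "blockSize", "dataType"}
#   <path>/<dataset>/<i>_<j>[_<k>]     raw little-endian float64, x fastest,
#                                      edge chunks clipped to the image.

.write_chunked <- function(vol, path, dataset, chunks) {
  if (is.null(dataset)) stop("chunked store output requires a dataset name")
  chunks <- as.integer(chunks[seq_len(vol$ndim)])
  stopifnot(all(chunks >= 1L))
  dsdir <- file.path(path, dataset)
  dir.create(dsdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(dimensions = vol$shape, blockSize = chunks, dataType = "float64"),
    file.path(dsdir, "attributes.json"), auto_unbox = FALSE)
  ngrid <- ceiling(vol$shape / chunks)
  grid <- as.matrix(expand.grid(lapply(ngrid, function(n) seq_len(n) - 1L)))
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    lo <- g * chunks + 1L
    hi <- pmin(lo + chunks - 1L, vol$shape)
    idx <- lapply(seq_len(vol$ndim), function(d) lo[d]:hi[d])
    block <- do.call(`[`, c(list(vol$data), idx, list(drop = FALSE)))
    con <- file(file.path(dsdir, paste(g, collapse = "_")), "wb")
    writeBin(as.double(block), con, size = 8L, endian = "little")
    close(con)
  }
  invisible(path)
}

.read_chunked <- function(path, dataset, lazy = FALSE) {
  if (is.null(dataset)) stop("reading a chunked store requires a dataset name")
  dsdir <- file.path(path, dataset)
  attr_file <- file.path(dsdir, "attributes.json")
  if (!file.exists(attr_file)) stop("no such dataset: ", dataset)
  at <- jsonlite::read_json(attr_file, simplifyVector = TRUE)
  shape <- as.integer(at$dimensions)
  nd <- length(shape)
  vol <- structure(
    list(data = NULL, shape = shape, ndim = nd,
         axes = c("x", "y", "z")[seq_len(nd)], spacing = NULL,
         backend = list(type = "chunked", dir = dsdir,
                        chunks = as.integer(at$blockSize))),
    class = "image_volume")
  if (lazy) return(vol)
  image_volume(.read_region_chunked(vol, rep(1L, nd), shape))
}

.read_region_chunked <- function(vol, lo, hi) {
  be <- vol$backend
  nd <- vol$ndim
  out <- array(0, dim = hi - lo + 1L)
  glo <- (lo - 1L) %/% be$chunks
  ghi <- (hi - 1L) %/% be$chunks
  grid <- as.matrix(expand.grid(lapply(seq_len(nd),
                                       function(d) glo[d]:ghi[d])))
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    clo <- g * be$chunks + 1L
    chi <- pmin(clo + be$chunks - 1L, vol$shape)
    f <- file.path(be$dir, paste(g, collapse = "_"))
    if (!file.exists(f)) stop("missing chunk file: ", f)
    con <- file(f, "rb")
    block <- readBin(con, "double", n = prod(chi - clo + 1L),
                     size = 8L, endian = "little")
    close(con)
    dim(block) <- chi - clo + 1L
    slo <- pmax(lo, clo); shi <- pmin(hi, chi)
    src <- lapply(seq_len(nd), function(d) (slo[d] - clo[d] + 1L):(shi[d] - clo[d] + 1L))
    dst <- lapply(seq_len(nd), function(d) (slo[d] - lo[d] + 1L):(shi[d] - lo[d] + 1L))
    piece <- do.call(`[`, c(list(block), src, list(drop = FALSE)))
    out <- do.call(`[<-`, c(list(out), dst, list(piece)))
  }
  out
}

# --- mirror extension -------------------------------------------------------

# Reflect an out-of-range 1-based index back into [1, n] without repeating
# the boundary sample (i = 0 -> 2, i = n + 1 -> n - 1).
.mirror_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  j <- (i - 1L) %% p
  j <- ifelse(j < 0L, j + p, j)
  as.integer(ifelse(j >= n, p - j, j) + 1L)
}

# Extract a region with mirror extension beyond image bounds.
.read_region_mirrored <- function(vol, lo, hi) {
  nd <- vol$ndim
  clo <- pmax(lo, 1L); chi <- pmin(hi, vol$shape)
  core <- read_region(vol, clo, chi)
  idx <- lapply(seq_len(nd), function(d) {
    .mirror_index(lo[d]:hi[d], vol$shape[d]) - clo[d] + 1L
  })
  # all mirrored indices fall inside the clamped core as long as the
  # overhang is < shape - 1 per axis, which holds for patch/filter margins
  if (any(vapply(idx, function(v) any(v < 1L), logical(1L))) ||
      any(mapply(function(v, m) any(v > m), idx, dim(core))))
    stop("mirror overhang exceeds image extent")
  do.call(`[`, c(list(core), idx, list(drop = FALSE)))
}
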