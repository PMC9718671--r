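# Block-wise execution: the image is tiled into half-open interior
# intervals that each own the seeds inside them; every block reads its
# interior plus a margin large enough for exact DoG values and maxima
# detection, while patches and intensities are read from the (lazy) full
# image.  Per-candidate RNG seeds derive from the global seed and the seed
# position, so detections are identical for every block layout.

#' Plan a block grid
#'
#' Interiors are half-open per-axis intervals `[lo, hi)` in pixel indices
#' (0-based) that tile the image exactly once; the last block per axis may
#' be smaller.  A block size larger than the image yields a single block.
#'
#' @param shape image extents
#' @param block_size per-axis block sizes (each >= 8)
#' @return a `block_grid`: list with `shape`, `block_size` and `blocks`,
#'   a list of `list(id, lo, hi)` records
#' @export
plan_blocks <- function(shape, block_size) {
  shape <- as.integer(shape)
  nd <- length(shape)
  block_size <- as.integer(block_size[seq_len(nd)])
  stopifnot(all(block_size >= 8L), all(shape >= 1L))
  starts <- lapply(seq_len(nd), function(d)
    seq.int(0L, shape[d] - 1L, by = block_size[d]))
  grid <- as.matrix(do.call(expand.grid, starts))
  blocks <- lapply(seq_len(nrow(grid)), function(r) {
    lo <- as.integer(grid[r, ])
    hi <- pmin(lo + block_size, shape)
    list(id = r, lo = lo, hi = hi)
  })
  structure(list(shape = shape, block_size = block_size, blocks = blocks),
            class = "block_grid")
}

#' Detect spots block by block
#'
#' Each block detects DoG seeds whose integer position lies in its
#' half-open interior, localizes them against the full (possibly lazy)
#' image, and tags its spots with the block id; the concatenated results
#' are redundancy-filtered globally.  Output is identical to
#' [detect_spots()] up to block bookkeeping, for every block layout.
#'
#' @param image an `image_volume`, in-memory or lazy (chunked store)
#' @param grid a [plan_blocks()] grid; derived from `config$block_size`
#'   when `NULL`
#' @param config a [run_config()]
#' @return detection `data.frame` as in [detect_spots()]
#' @export
detect_blockwise <- function(image, grid = NULL, config = run_config()) {
  stopifnot(inherits(image, "image_volume"))
  if (is.null(grid)) grid <- plan_blocks(image$shape, config$block_size)
  stopifnot(inherits(grid, "block_grid"),
            all(grid$shape == image$shape))
  nd <- image$ndim
  dogp <- dog_params(config$sigma, config$dog_k, config$threshold,
                     config$anisotropy)
  # margin per axis: DoG kernel half-width of the wider Gaussian, plus the
  # 1-pixel neighborhood needed for strict-maximum detection
  sig <- rep(config$sigma, nd)
  if (nd == 3L) sig[3L] <- config$sigma / config$anisotropy
  margin <- vapply(config$dog_k * sig,
                   function(s) max(1L, as.integer(ceiling(3 * s))),
                   integer(1L)) + 1L
  pos_cols <- c("x", "y", "z")[seq_len(nd)]
  all_spots <- list()
  for (blk in grid$blocks) {
    spots <- tryCatch(
      .detect_block(image, blk, margin, dogp, config, pos_cols),
      error = function(e)
        stop("block ", blk$id, ": ", conditionMessage(e), call. = FALSE))
    if (nrow(spots) > 0L) all_spots[[length(all_spots) + 1L]] <- spots
  }
  spots <- if (length(all_spots) == 0L) .empty_spots(nd)
           else do.call(rbind, all_spots)
  spots <- redundancy_filter(spots, config$min_separation)
  rownames(spots) <- NULL
  spots
}

.detect_block <- function(image, blk, margin, dogp, config, pos_cols) {
  nd <- image$ndim
  # read region: interior +/- margin, clamped to the image (the image's
  # own mirror boundary then coincides with the block's)
  rlo <- pmax(blk$lo - margin, 0L)
  rhi <- pmin(blk$hi + margin, image$shape)
  local <- image_volume(read_region(image, rlo + 1L, rhi))
  seeds <- find_seeds(dog_filter(local, dogp), dogp$threshold)
  if (nrow(seeds) > 0L) {
    pos <- as.matrix(seeds[, pos_cols, drop = FALSE]) +
      matrix(rlo, nrow(seeds), nd, byrow = TRUE)
    own <- rowSums(pos >= matrix(blk$lo, nrow(pos), nd, byrow = TRUE) &
                   pos <  matrix(blk$hi, nrow(pos), nd, byrow = TRUE)) == nd
    seeds <- seeds[own, , drop = FALSE]
    if (nrow(seeds) > 0L) seeds[, pos_cols] <- pos[own, , drop = FALSE]
  }
  .process_seeds(image, seeds, config, block_id = blk$id)
}
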