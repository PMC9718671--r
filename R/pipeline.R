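# The full detection pipeline: DoG seeding -> per-seed gradient field ->
# radial-symmetry fit (optionally RANSAC) -> postprocessing.

#' Detection run configuration
#'
#' All detector parameters with their defaults.  `sigma` and `threshold`
#' must be adjusted to the average spot size and intensity of the data;
#' the remaining defaults suit typical smFISH acquisitions.
#'
#' @param sigma lateral DoG sigma in pixels
#' @param dog_k DoG sigma ratio
#' @param threshold DoG seed threshold (image intensity units)
#' @param support_radius gradient support region radius r (patch side
#'   `2r + 1`)
#' @param background background correction for patches: `"none"` or
#'   `"plane"`
#' @param anisotropy global axial anisotropy factor `a`
#' @param ransac `"off"`, `"single"` or `"multi"`
#' @param epsilon RANSAC inlier distance in pixels (scaled space)
#' @param min_inliers minimal RANSAC consensus size
#' @param max_iterations RANSAC sampling cap
#' @param confidence RANSAC adaptive-stop confidence
#' @param weights gradient weighting: `"magnitude2"`, `"magnitude"` or
#'   `"uniform"`
#' @param min_separation redundancy-filter distance in pixels
#' @param intensity `"interpolate"` or `"gauss_refit"`
#' @param block_size per-axis block sizes for block-wise execution
#' @param seed global RNG seed; every per-spot RANSAC stream is derived
#'   from it and the seed position, so results do not depend on block
#'   layout or traversal order
#' @return a `run_config` list
#' @export
run_config <- function(sigma = 1.5, dog_k = 1.6, threshold = 0.007,
                       support_radius = 3L, background = "none",
                       anisotropy = 1.0, ransac = "single",
                       epsilon = 0.5, min_inliers = 30L,
                       max_iterations = 1000L, confidence = 0.99,
                       weights = "magnitude2", min_separation = 0.5,
                       intensity = "interpolate",
                       block_size = c(256L, 256L, 128L), seed = 42L) {
  cfg <- list(sigma = sigma, dog_k = dog_k, threshold = threshold,
              support_radius = as.integer(support_radius),
              background = match.arg(background, c("none", "plane")),
              anisotropy = anisotropy,
              ransac = match.arg(ransac, c("off", "single", "multi")),
              epsilon = epsilon, min_inliers = as.integer(min_inliers),
              max_iterations = as.integer(max_iterations),
              confidence = confidence,
              weights = match.arg(weights,
                                  c("magnitude2", "magnitude", "uniform")),
              min_separation = min_separation,
              intensity = match.arg(intensity,
                                    c("interpolate", "gauss_refit")),
              block_size = as.integer(block_size),
              seed = as.integer(seed))
  stopifnot(cfg$sigma > 0, cfg$dog_k > 1, cfg$threshold >= 0,
            cfg$support_radius >= 1L, cfg$anisotropy > 0, cfg$epsilon > 0,
            cfg$min_inliers >= 2L, cfg$min_separation >= 0)
  structure(cfg, class = c("run_config", "list"))
}

#' Detect spots in an image
#'
#' Runs the full pipeline on an in-memory image: DoG seeding, per-seed
#' gradient extraction (optionally background-corrected), radial-symmetry
#' localization with the configured RANSAC mode, redundancy filtering, and
#' intensity measurement.  Fitted centers that leave the support patch are
#' discarded as unsupported by the data.
#'
#' @param image an `image_volume`
#' @param config a [run_config()]
#' @return `data.frame` with columns `x,y,z,t,c,intensity` plus
#'   `n_inliers`, `mean_residual` and `block_id`
#' @export
detect_spots <- function(image, config = run_config()) {
  stopifnot(inherits(image, "image_volume"))
  dogp <- dog_params(config$sigma, config$dog_k, config$threshold,
                     config$anisotropy)
  seeds <- find_seeds(dog_filter(image, dogp), config$threshold)
  spots <- .process_seeds(image, seeds, config, block_id = 0L)
  spots <- redundancy_filter(spots, config$min_separation)
  rownames(spots) <- NULL
  spots
}

.empty_spots <- function(ndim) {
  data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
             t = integer(0), c = integer(0), intensity = numeric(0),
             n_inliers = integer(0), mean_residual = numeric(0),
             block_id = integer(0))
}

# Localize every seed; `image` may be lazy — only patch-sized regions are
# read.  Seed coordinates are global, so derived RNG seeds (and therefore
# results) are independent of any block decomposition.
.process_seeds <- function(image, seeds, config, block_id = 0L) {
  nd <- image$ndim
  scale <- anisotropy_scale(config$anisotropy)
  rows <- list()
  pos_cols <- c("x", "y", "z")[seq_len(nd)]
  for (i in seq_len(nrow(seeds))) {
    seed_pos <- as.integer(seeds[i, pos_cols])
    patch <- support_patch(image, seed_pos, config$support_radius)
    patch <- subtract_background(patch, config$background)
    field <- compute_gradients(patch)
    # gradients built on mirror padding duplicate interior data and would
    # bias (and ghost-duplicate) border fits — localize on real data only
    if (any(field$fabricated))
      field <- .field_subset(field, which(!field$fabricated))
    if (field$n < 2L) next
    sets <- .localize_candidate(field, scale, config, seed_pos)
    for (cs in sets) {
      ctr <- cs$center
      if (any(!is.finite(ctr))) next
      # a center outside the support patch is not supported by its data
      if (any(abs(ctr - seed_pos) > config$support_radius + 0.5)) next
      # an edge seed sees the spot and its mirror image; a center that
      # landed in the mirror padding is the ghost — reflect it back
      ctr <- ifelse(ctr < 0, -ctr, ctr)
      ctr <- ifelse(ctr > image$shape - 1L,
                    2 * (image$shape - 1L) - ctr, ctr)
      if (any(ctr < 0) || any(ctr > image$shape - 1L)) next
      inten <- if (config$intensity == "gauss_refit")
        measure_intensity(image, ctr, "gauss_refit",
                          inlier_positions =
                            field$positions[cs$inliers, , drop = FALSE],
                          sigma = config$sigma,
                          anisotropy = config$anisotropy)
      else measure_intensity(image, ctr, "interpolate")
      rows[[length(rows) + 1L]] <-
        data.frame(x = ctr[1L], y = ctr[2L],
                   z = if (nd == 3L) ctr[3L] else 0,
                   t = 1L, c = 1L, intensity = inten,
                   n_inliers = cs$n_inliers,
                   mean_residual = cs$mean_residual,
                   block_id = block_id)
    }
  }
  if (length(rows) == 0L) return(.empty_spots(nd))
  do.call(rbind, rows)
}

# Run the configured localization mode on one candidate gradient field.
# Returns a list of consensus-set-like records.
.localize_candidate <- function(field, scale, config, seed_pos) {
  if (config$ransac == "off") {
    fit <- tryCatch(fit_center(field, scale, config$weights),
                    error = function(e) NULL)
    if (is.null(fit)) return(list())
    return(list(list(center = fit$center, inliers = fit$used,
                     n_inliers = 0L,
                     mean_residual = mean(fit$residuals))))
  }
  rp <- ransac_params(epsilon = config$epsilon,
                      min_inliers = config$min_inliers,
                      max_iterations = config$max_iterations,
                      confidence = config$confidence,
                      multi_consensus = config$ransac == "multi",
                      rng_seed = .derive_seed(config$seed, seed_pos))
  if (config$ransac == "single") {
    cs <- ransac_single(field, scale, rp, config$weights)
    if (is.null(cs)) return(list())
    return(list(cs))
  }
  ransac_multi(field, scale, rp, config$weights)
}

#' Detect spots in an image file and write a CSV detection table
#'
#' Thin wrapper around [read_image()], [detect_spots()] /
#' [detect_blockwise()] and [write_detections()].  A sidecar
#' `<output>.json` with the fully resolved configuration and package
#' version is written next to every table.  On error any partial output
#' is removed.
#'
#' @param input image path (TIFF or chunked store)
#' @param output CSV output path
#' @param config a [run_config()]
#' @param dataset dataset name for chunked stores
#' @param blockwise process block-wise (automatic for chunked stores)
#' @return the detection `data.frame`, invisibly
#' @export
detect_file <- function(input, output, config = run_config(),
                        dataset = NULL, blockwise = NULL) {
  lazy <- dir.exists(input)
  image <- read_image(input, dataset = dataset, lazy = lazy)
  if (is.null(blockwise)) blockwise <- lazy
  ok <- FALSE
  on.exit(if (!ok) unlink(c(output, paste0(output, ".json"))))
  spots <- if (blockwise)
    detect_blockwise(image, config = config)
  else detect_spots(image, config)
  n <- write_detections(spots, output)
  jsonlite::write_json(
    list(config = unclass(config),
         package = "radialspots",
         version = as.character(utils::packageVersion("radialspots")),
         n_spots = n),
    paste0(output, ".json"), auto_unbox = TRUE, pretty = TRUE)
  message(sprintf("detected %d spots -> %s", n, output))
  ok <- TRUE
  invisible(spots)
}
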