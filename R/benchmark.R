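# Detection/localization benchmark: one-to-one greedy matching of
# detections to ground truth, F1 score, per-axis signed offsets ("precision"
# in the coordinate-convention sense), Euclidean error, grid search.

#' Match detections against ground truth
#'
#' Pairs are formed greedily by ascending Euclidean distance among all
#' (truth, detection) pairs closer than `max_distance`, one-to-one.
#' True/false positives and false negatives follow from the matching;
#' `f1 = 2 tp / (2 tp + fp + fn)`.
#'
#' @param truth `data.frame` with coordinate columns `x`, `y` (and `z`)
#' @param detected `data.frame` of detections with the same columns
#' @param max_distance maximal matching distance in pixels
#' @return a `benchmark_result` list: `tp`, `fp`, `fn`, `f1`, `matches`
#'   (`data.frame` of pair indices, per-axis deltas detection - truth, and
#'   distance), `mean_euclidean_error`, `per_axis_offset`
#' @export
match_detections <- function(truth, detected, max_distance = 3.0) {
  stopifnot(max_distance > 0)
  truth <- as.data.frame(truth); detected <- as.data.frame(detected)
  cols <- intersect(intersect(c("x", "y", "z"), names(truth)),
                    names(detected))
  Tm <- as.matrix(truth[, cols, drop = FALSE])
  Dm <- as.matrix(detected[, cols, drop = FALSE])
  nt <- nrow(Tm); ndet <- nrow(Dm)
  pairs <- NULL
  if (nt > 0L && ndet > 0L) {
    d2 <- outer(rowSums(Tm^2), rep(1, ndet)) +
      outer(rep(1, nt), rowSums(Dm^2)) - 2 * Tm %*% t(Dm)
    d <- sqrt(pmax(d2, 0))   # d2 first so the matrix shape survives pmax
    cand <- which(d < max_distance, arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      cand <- cand[order(d[cand]), , drop = FALSE]
      t_used <- logical(nt); d_used <- logical(ndet)
      rows <- list()
      for (r in seq_len(nrow(cand))) {
        ti <- cand[r, 1L]; di <- cand[r, 2L]
        if (t_used[ti] || d_used[di]) next
        t_used[ti] <- TRUE; d_used[di] <- TRUE
        rows[[length(rows) + 1L]] <- c(ti, di, Dm[di, ] - Tm[ti, ],
                                       d[ti, di])
      }
      if (length(rows) > 0L) {
        pairs <- as.data.frame(do.call(rbind, rows))
        names(pairs) <- c("truth_idx", "det_idx",
                          paste0("d", cols), "distance")
      }
    }
  }
  tp <- if (is.null(pairs)) 0L else nrow(pairs)
  fp <- ndet - tp
  fn <- nt - tp
  f1 <- if (tp + fp + fn > 0L) 2 * tp / (2 * tp + fp + fn) else NA_real_
  offs <- if (tp > 0L)
    colMeans(pairs[, paste0("d", cols), drop = FALSE]) else
      stats::setNames(rep(NA_real_, length(cols)), paste0("d", cols))
  structure(list(tp = tp, fp = fp, fn = fn, f1 = f1, matches = pairs,
                 mean_euclidean_error =
                   if (tp > 0L) mean(pairs$distance) else NA_real_,
                 per_axis_offset = offs, axes = cols),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> tp=%d fp=%d fn=%d F1=%.4f\n",
              x$tp, x$fp, x$fn, x$f1))
  if (x$tp > 0L)
    cat(sprintf("  mean Euclidean error %.4f px; per-axis offset [%s]\n",
                x$mean_euclidean_error,
                paste(sprintf("%.4f", x$per_axis_offset), collapse = ", ")))
  invisible(x)
}

#' Remove a systematic per-axis offset from detections
#'
#' Subtracts the mean signed per-dimension difference between matched
#' detections and truth from every detection — the standard correction for
#' pixel-origin convention mismatches between tools.
#'
#' @param result a [match_detections()] result with at least one match
#' @param detected the detection `data.frame` the result was computed from
#' @return `detected` with shifted coordinate columns
#' @export
correct_offset <- function(result, detected) {
  stopifnot(inherits(result, "benchmark_result"))
  if (result$tp < 1L) stop("offset correction requires at least one match")
  detected <- as.data.frame(detected)
  for (i in seq_along(result$axes)) {
    ax <- result$axes[i]
    detected[[ax]] <- detected[[ax]] - result$per_axis_offset[[i]]
  }
  detected
}

#' Detection-parameter grid search over simulated scenes
#'
#' Runs the full detector for every grid point on every scene and
#' aggregates F1 and localization error (unweighted mean over scenes).
#' The best point maximizes mean F1, ties broken by lower mean error.
#'
#' @param scenes list of `simulated_scene` objects
#' @param grid `data.frame` whose columns are [run_config()] fields to
#'   override (one row per grid point)
#' @param config base [run_config()] supplying all other parameters
#' @param max_distance matching radius passed to [match_detections()]
#' @return list with `table` (per-point mean F1/error, failures marked in
#'   an `error` column) and `best` (the argmax row)
#' @export
grid_search <- function(scenes, grid, config = run_config(),
                        max_distance = 3.0) {
  if (length(scenes) == 0L) stop("grid search needs at least one scene")
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0L) stop("empty parameter grid")
  res <- grid
  res$mean_f1 <- NA_real_
  res$f1_ci95 <- NA_real_      # normal-approximation half-width over scenes
  res$mean_error <- NA_real_
  res$error <- NA_character_
  for (g in seq_len(nrow(grid))) {
    cfg <- utils::modifyList(config, as.list(grid[g, , drop = FALSE]))
    f1s <- errs <- numeric(0)
    fail <- NULL
    for (sc in scenes) {
      out <- tryCatch(detect_spots(sc$image, cfg), error = identity)
      if (inherits(out, "error")) { fail <- conditionMessage(out); break }
      bm <- match_detections(sc$truth, out, max_distance)
      f1s <- c(f1s, bm$f1)
      errs <- c(errs, if (bm$tp > 0L) bm$mean_euclidean_error else NA_real_)
    }
    if (!is.null(fail)) { res$error[g] <- fail; next }
    res$mean_f1[g] <- mean(f1s)
    if (length(f1s) > 1L)
      res$f1_ci95[g] <- 1.96 * stats::sd(f1s) / sqrt(length(f1s))
    res$mean_error[g] <- mean(errs, na.rm = TRUE)
  }
  ok <- which(is.na(res$error))
  if (length(ok) == 0L) return(list(table = res, best = NULL))
  best <- ok[order(-res$mean_f1[ok], res$mean_error[ok])][1L]
  list(table = res, best = res[best, , drop = FALSE])
}
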