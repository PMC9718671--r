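# Detection tables: one row per spot with header exactly
# "x,y,z,t,c,intensity".  z is written as 0 for 2D images; t and c default
# to 1 (single frame, single channel).

.DETECTION_HEADER <- c("x", "y", "z", "t", "c", "intensity")

#' Write a detection table to CSV
#'
#' Columns are `x,y,z,t,c,intensity`; coordinates are written with 6
#' decimal places ('.' decimal separator, Unix newlines) so files are
#' stable across platforms.
#'
#' @param spots a `data.frame` of spots as returned by [detect_spots()]
#'   (needs at least `x`, `y` and `intensity`; `z` defaults to 0, `t` and
#'   `c` to 1)
#' @param path output CSV path
#' @return the number of data rows written (invisibly)
#' @export
write_detections <- function(spots, path) {
  spots <- as.data.frame(spots)
  n <- nrow(spots)
  if (n > 0L) {
    for (col in c("x", "y")) if (is.null(spots[[col]]))
      stop("spots are missing column ", col)
    if (!all(is.finite(spots$x)) || !all(is.finite(spots$y)))
      stop("spot coordinates must be finite")
  }
  if (is.null(spots$z)) spots$z <- rep(0, n)
  if (is.null(spots$t)) spots$t <- rep(1L, n)
  if (is.null(spots$c)) spots$c <- rep(1L, n)
  if (is.null(spots$intensity)) spots$intensity <- rep(NA_real_, n)
  con <- file(path, "wb")   # binary connection -> Unix newlines everywhere
  on.exit(close(con))
  writeLines(paste(.DETECTION_HEADER, collapse = ","), con, sep = "\n")
  if (n > 0L) {
    lines <- sprintf("%.6f,%.6f,%.6f,%d,%d,%.6f",
                     spots$x, spots$y, spots$z,
                     as.integer(spots$t), as.integer(spots$c),
                     spots$intensity)
    writeLines(lines, con, sep = "\n")
  }
  invisible(n)
}

#' Read a detection table written by [write_detections()]
#' @param path CSV path
#' @return `data.frame` with columns `x,y,z,t,c,intensity`
#' @export
read_detections <- function(path) {
  df <- utils::read.csv(path, colClasses = c(x = "numeric", y = "numeric",
                                             z = "numeric", t = "integer",
                                             c = "integer",
                                             intensity = "numeric"))
  if (!identical(names(df), .DETECTION_HEADER))
    stop("unexpected detection table header in ", path)
  df
}
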