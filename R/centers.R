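#' Cone centre set
#'
#' A validated set of cone centre coordinates within an ROI. Coordinates are
#' 0-based pixel units, x rightwards and y downwards, with pixel centres at
#' integer positions; every centre must lie inside the half-open ROI bounds
#' and no two centres may lie within 0.5 px of each other.
#'
#' @param roi An [roi_spec()].
#' @param x,y Numeric vectors of equal length: centre coordinates in pixels.
#' @return A `cone_centers` object with fields `roi`, `x`, `y`.
#' @export
cone_centers <- function(roi, x, y) {
  stopifnot(inherits(roi, "roi_spec"), length(x) == length(y))
  x <- as.numeric(x); y <- as.numeric(y)
  bad <- which(!is.finite(x) | !is.finite(y) |
                 x < 0 | x >= roi$width_px | y < 0 | y >= roi$height_px)
  if (length(bad)) {
    stop("centre(s) outside ROI bounds [0, ", roi$width_px, ") x [0, ",
         roi$height_px, ") at index: ", paste(bad, collapse = ", "))
  }
  dup <- close_pairs(x, y, 0.5)
  if (length(dup)) {
    stop("centres closer than 0.5 px (duplicates) at index: ",
         paste(dup, collapse = ", "))
  }
  structure(list(roi = roi, x = x, y = y), class = "cone_centers")
}

#' @export
print.cone_centers <- function(x, ...) {
  cat(sprintf("<cone_centers> %d cones in %d x %d px ROI\n",
              length(x$x), x$roi$width_px, x$roi$height_px))
  invisible(x)
}

#' @export
length.cone_centers <- function(x) length(x$x)

# indices of points having an earlier point within `tol` px
close_pairs <- function(x, y, tol) {
  n <- length(x)
  if (n < 2L) return(integer())
  # grid hash at cell size tol keeps this O(n) for realistic mosaics
  ord <- order(y, x)
  flagged <- logical(n)
  cx <- floor(x / tol); cy <- floor(y / tol)
  key <- paste(cx, cy)
  buckets <- split(seq_len(n), key)
  for (i in seq_len(n)) {
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(cx[i] + dx, cy[i] + dy)
      js <- buckets[[k]]
      js <- js[js < i]
      if (length(js) && any((x[js] - x[i])^2 + (y[js] - y[i])^2 < tol^2)) {
        flagged[i] <- TRUE
      }
    }
  }
  which(flagged)
}

#' Read cone centres from a delimited text file
#'
#' Expects comma-separated text with a header line naming columns `x` and
#' `y`, coordinates in pixels. Malformed rows, out-of-bounds points and
#' duplicate coordinate pairs are reported with their (1-based, data) row
#' numbers.
#'
#' @param path Path to the CSV file.
#' @param roi The [roi_spec()] the coordinates refer to.
#' @return A [cone_centers()] object.
#' @export
read_centers <- function(path, roi) {
  stopifnot(file.exists(path))
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e)))
  if (nrow(df) == 0L) stop("empty centre file: ", path)
  if (!all(c("x", "y") %in% names(df))) {
    stop("centre file must have header columns 'x' and 'y': ", path)
  }
  x <- suppressWarnings(as.numeric(df$x))
  y <- suppressWarnings(as.numeric(df$y))
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad)) {
    stop("malformed coordinate(s) in ", path, " at row: ",
         paste(bad, collapse = ", "))
  }
  oob <- which(x < 0 | x >= roi$width_px | y < 0 | y >= roi$height_px)
  if (length(oob)) {
    stop("out-of-bounds centre(s) in ", path, " at row: ",
         paste(oob, collapse = ", "),
         " (bounds are half-open [0, width) x [0, height))")
  }
  dup <- close_pairs(x, y, 0.5)
  if (length(dup)) {
    stop("duplicate centre(s) in ", path, " at row: ",
         paste(dup, collapse = ", "))
  }
  cone_centers(roi, x, y)
}

#' Write cone centres to CSV
#'
#' Inverse of [read_centers()]: a two-column `x,y` CSV in pixel units.
#'
#' @param centers A [cone_centers()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_centers <- function(centers, path) {
  stopifnot(inherits(centers, "cone_centers"))
  utils::write.csv(data.frame(x = centers$x, y = centers$y), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
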