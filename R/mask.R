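#' Cone segmentation label mask
#'
#' An integer raster of a completed cone inner-segment segmentation: 0 marks
#' background (intercone space) and k > 0 marks the pixels occupied by the
#' k-th cone. Stored as an R matrix `labels[row, col]` where row = y + 1 and
#' col = x + 1 in the 0-based pixel convention. Labels are relabelled to a
#' contiguous 1..K by order of first appearance in a row-major scan.
#'
#' @param roi An [roi_spec()]; its dimensions must match `labels`.
#' @param labels Integer matrix, `height_px` rows by `width_px` columns,
#'   non-negative values.
#' @return A `cone_mask` object with fields `roi`, `labels`, `n_cones`.
#' @export
cone_mask <- function(roi, labels) {
  stopifnot(inherits(roi, "roi_spec"), is.matrix(labels))
  if (nrow(labels) != roi$height_px || ncol(labels) != roi$width_px) {
    stop("label matrix is ", nrow(labels), " x ", ncol(labels),
         " but ROI is ", roi$height_px, " x ", roi$width_px)
  }
  if (any(!is.finite(labels)) || any(labels < 0) ||
      any(labels != floor(labels))) {
    stop("labels must be non-negative integers")
  }
  storage.mode(labels) <- "integer"
  labels <- relabel_rowmajor(labels)
  structure(list(roi = roi, labels = labels, n_cones = max(labels, 0L)),
            class = "cone_mask")
}

#' @export
print.cone_mask <- function(x, ...) {
  cat(sprintf("<cone_mask> %d cones, %d x %d px\n",
              x$n_cones, x$roi$width_px, x$roi$height_px))
  invisible(x)
}

# Relabel to contiguous 1..K in order of first appearance scanning rows
# left-to-right, top-to-bottom.
relabel_rowmajor <- function(labels) {
  v <- as.vector(t(labels))           # row-major order
  nz <- v[v > 0L]
  if (!length(nz)) return(labels)
  first <- nz[!duplicated(nz)]
  lut <- integer(max(first))
  lut[first] <- seq_along(first)
  labels[labels > 0L] <- lut[labels[labels > 0L]]
  labels
}

#' Read a label mask from a grayscale PNG or TIFF
#'
#' The image must be single-channel with integer values; 0 is background.
#' Labels are made contiguous (1..K, row-major first appearance). 8- and
#' 16-bit PNG and 8/16-bit integer TIFF are accepted; multi-channel or
#' float-valued images are rejected.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param roi An [roi_spec()] giving the scale; its pixel dimensions must
#'   match the image.
#' @return A [cone_mask()].
#' @export
read_label_mask <- function(path, roi) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    if (length(dim(img)) != 2L) {
      stop("mask must be single-channel grayscale, got ",
           dim(img)[3], " channels: ", path)
    }
    depth <- attr(img, "info")$bit.depth
    raw <- img * (2^depth - 1)
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) != 2L) {
      stop("mask must be single-channel grayscale, got ",
           dim(img)[3], " channels: ", path)
    }
    raw <- img
  } else {
    stop("unsupported mask format '", ext, "' (use PNG or TIFF)")
  }
  if (max(abs(raw - round(raw))) > 1e-6) {
    stop("mask pixel values are not integers (float-valued image): ", path)
  }
  if (any(raw < 0)) {
    stop("negative pixel values (not a label mask): ", path)
  }
  cone_mask(roi, matrix(as.integer(round(raw)), nrow(raw), ncol(raw)))
}

#' Write a label mask as 16-bit grayscale TIFF
#'
#' Lossless for up to 65535 cones; [read_label_mask()] recovers the mask
#' exactly (masks are stored with contiguous labels, so the round trip is
#' the identity).
#'
#' @param mask A [cone_mask()].
#' @param path Output path (`.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(inherits(mask, "cone_mask"))
  if (mask$n_cones > 65535L) stop("more than 65535 labels")
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Reconcile cone centres with a segmentation mask
#'
#' Maps each centre to the label of the pixel it falls in. Centres landing
#' on background are assigned the nearest labelled pixel within 3 px;
#' otherwise they are flagged unmatched. If several centres claim one label,
#' only the first keeps it and the rest are flagged.
#'
#' @param centers A [cone_centers()].
#' @param mask A [cone_mask()] with the same ROI dimensions.
#' @return A data frame with one row per centre: `center`, `label` (NA when
#'   unmatched), and `flag` (`"ok"`, `"unmatched"`, or `"duplicate"`).
#' @export
match_centers_to_labels <- function(centers, mask) {
  stopifnot(inherits(centers, "cone_centers"), inherits(mask, "cone_mask"))
  roi <- centers$roi
  if (roi$width_px != mask$roi$width_px || roi$height_px != mask$roi$height_px) {
    stop("centers and mask refer to different ROI dimensions")
  }
  L <- mask$labels
  n <- length(centers$x)
  lab <- rep(NA_integer_, n)
  flag <- rep("ok", n)
  px <- pmin(pmax(round(centers$x), 0), roi$width_px - 1L)
  py <- pmin(pmax(round(centers$y), 0), roi$height_px - 1L)
  for (i in seq_len(n)) {
    l <- L[py[i] + 1L, px[i] + 1L]
    if (l == 0L) {
      l <- nearest_label(L, centers$x[i], centers$y[i], max_dist = 3)
    }
    if (is.na(l) || l == 0L) {
      flag[i] <- "unmatched"
    } else {
      lab[i] <- l
    }
  }
  dup <- !is.na(lab) & duplicated(lab, incomparables = NA)
  flag[dup] <- "duplicate"
  lab[dup] <- NA_integer_
  data.frame(center = seq_len(n), label = lab, flag = flag,
             stringsAsFactors = FALSE)
}

# nearest non-zero label within max_dist px of point (x, y); NA if none
nearest_label <- function(L, x, y, max_dist = 3) {
  h <- nrow(L); w <- ncol(L)
  x0 <- max(0L, floor(x - max_dist)); x1 <- min(w - 1L, ceiling(x + max_dist))
  y0 <- max(0L, floor(y - max_dist)); y1 <- min(h - 1L, ceiling(y + max_dist))
  xs <- x0:x1; ys <- y0:y1
  sub <- L[ys + 1L, xs + 1L, drop = FALSE]
  idx <- which(sub > 0L, arr.ind = TRUE)
  if (!nrow(idx)) return(NA_integer_)
  d2 <- (ys[idx[, 1]] - y)^2 + (xs[idx[, 2]] - x)^2
  ok <- d2 <= max_dist^2
  if (!any(ok)) return(NA_integer_)
  vals <- sub[idx]
  vals[ok][which.min(d2[ok])]
}
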