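#' Retinal magnification: microns per degree of visual angle
#'
#' Converts axial length to a linear retinal scale using the first-order
#' (Emsley-style) convention of 291 um/deg for a 24.0 mm emmetropic eye,
#' scaled proportionally with axial length. This is the standard first-order
#' scaling used to set the image scale of AOSLO frames from an ocular
#' biometry (IOLMaster) axial length.
#'
#' @param axial_length_mm Axial length of the imaged eye in millimetres.
#'   Must lie in the physiologic range (15, 35).
#' @return Retinal scale in micrometres per degree.
#' @examples
#' microns_per_degree(24)   # 291
#' microns_per_degree(26)   # 315.25
#' @export
microns_per_degree <- function(axial_length_mm) {
  stopifnot(is.numeric(axial_length_mm), length(axial_length_mm) == 1L)
  if (!is.finite(axial_length_mm) ||
      axial_length_mm <= 15 || axial_length_mm >= 35) {
    stop("axial_length_mm must be in the physiologic range (15, 35) mm, got ",
         format(axial_length_mm))
  }
  291.0 * (axial_length_mm / 24.0)
}

#' Pixel scale of an AOSLO frame
#'
#' Image scale in micrometres per pixel for a raster of `pixels_per_line`
#' pixels spanning `fov_deg` degrees, in an eye of the given axial length.
#'
#' @param axial_length_mm Axial length in mm (see [microns_per_degree()]).
#' @param fov_deg Field of view of the scan, degrees. Default 1.
#' @param pixels_per_line Pixels across the field. Default 582, which gives
#'   0.5 um/px at a 24 mm axial length and 1 degree field.
#' @return Scale in micrometres per pixel.
#' @examples
#' microns_per_pixel(24, 1, 582)  # 0.5
#' @export
microns_per_pixel <- function(axial_length_mm, fov_deg = 1, pixels_per_line = 582L) {
  stopifnot(is.numeric(fov_deg), length(fov_deg) == 1L,
            is.numeric(pixels_per_line), length(pixels_per_line) == 1L)
  if (!is.finite(fov_deg) || fov_deg <= 0) {
    stop("fov_deg must be positive")
  }
  if (!is.finite(pixels_per_line) || pixels_per_line <= 0) {
    stop("pixels_per_line must be positive")
  }
  microns_per_degree(axial_length_mm) * fov_deg / pixels_per_line
}

#' Region-of-interest specification
#'
#' Describes the geometry of a rectangular ROI cropped from an AOSLO montage:
#' its size in pixels, retinal eccentricity, and pixel scale. The pixel grid
#' is 0-based with pixel centres at integer coordinates; ROI bounds are
#' half-open, `[0, width_px) x [0, height_px)`.
#'
#' @param width_px,height_px ROI size in pixels (integers, each >= 16).
#' @param eccentricity_deg Temporal retinal eccentricity in degrees
#'   (non-negative).
#' @param microns_per_pixel Pixel scale in um/px (> 0).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(width_px, height_px, eccentricity_deg = 0,
                     microns_per_pixel = 0.5) {
  width_px <- as.integer(width_px)
  height_px <- as.integer(height_px)
  if (is.na(width_px) || is.na(height_px) || width_px < 16L || height_px < 16L) {
    stop("ROI must be at least 16 x 16 pixels")
  }
  if (!is.finite(eccentricity_deg) || eccentricity_deg < 0) {
    stop("eccentricity_deg must be non-negative")
  }
  if (!is.finite(microns_per_pixel) || microns_per_pixel <= 0) {
    stop("microns_per_pixel must be positive")
  }
  structure(
    list(width_px = width_px, height_px = height_px,
         eccentricity_deg = as.numeric(eccentricity_deg),
         microns_per_pixel = as.numeric(microns_per_pixel)),
    class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("<roi_spec> %d x %d px, %.4g um/px, %g deg temporal\n",
              x$width_px, x$height_px, x$microns_per_pixel,
              x$eccentricity_deg))
  invisible(x)
}

# ROI area in mm^2 (pixel count times squared scale)
roi_area_mm2 <- function(roi) {
  roi$width_px * roi$height_px * (roi$microns_per_pixel * 1e-3)^2
}

#' Subject record
#'
#' Metadata for one study participant: identifier, disease group and axial
#' length of the imaged eye.
#'
#' @param subject_id Character identifier.
#' @param group Either `"control"` or `"CHM"`.
#' @param axial_length_mm Axial length in mm, in (15, 35).
#' @return A `subject_record` list.
#' @export
subject_record <- function(subject_id, group, axial_length_mm = 24) {
  group <- match.arg(group, c("control", "CHM"))
  microns_per_degree(axial_length_mm)  # range check
  structure(list(subject_id = as.character(subject_id), group = group,
                 axial_length_mm = as.numeric(axial_length_mm)),
            class = "subject_record")
}
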