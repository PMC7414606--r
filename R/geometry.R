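#' Scan geometry of an en face OCTA acquisition
#'
#' Describes the transverse geometry of a square en face scan: field of view
#' in millimetres, grid size in pixels, and the angular calibration used to
#' convert visual degrees to retinal distance.  The defaults correspond to a
#' 6 x 6 mm macular scan sampled on a 500 x 500 grid at a calibration of
#' 3.5 degrees per millimetre, which gives a transverse pixel size of exactly
#' 12 um.
#'
#' @param field_of_view_mm Side length of the square field of view, in mm.
#' @param grid_size_px Number of pixels along each side of the raster grid.
#' @param degrees_per_mm Angular calibration: visual degrees per millimetre
#'   of retina.
#'
#' @return An object of class `scan_geometry` with fields
#'   `field_of_view_mm`, `grid_size_px`, `degrees_per_mm` and the derived
#'   `pixel_size_um`.
#' @examples
#' g <- scan_geometry()
#' g$pixel_size_um   # 12
#' pixels_to_um(40, g)  # 480
#' @export
scan_geometry <- function(field_of_view_mm = 6, grid_size_px = 500L,
                          degrees_per_mm = 3.5) {
  if (!is.numeric(field_of_view_mm) || field_of_view_mm <= 0)
    stop("'field_of_view_mm' must be strictly positive")
  if (!is.numeric(grid_size_px) || grid_size_px <= 0 ||
      grid_size_px != round(grid_size_px))
    stop("'grid_size_px' must be a strictly positive integer")
  if (!is.numeric(degrees_per_mm) || degrees_per_mm <= 0)
    stop("'degrees_per_mm' must be strictly positive")
  structure(list(
    field_of_view_mm = as.numeric(field_of_view_mm),
    grid_size_px = as.integer(grid_size_px),
    degrees_per_mm = as.numeric(degrees_per_mm),
    pixel_size_um = field_of_view_mm * 1000 / grid_size_px
  ), class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("Scan geometry: %.3g x %.3g mm, %d x %d px (%.4g um/px), %.3g deg/mm\n",
              x$field_of_view_mm, x$field_of_view_mm,
              x$grid_size_px, x$grid_size_px,
              x$pixel_size_um, x$degrees_per_mm))
  invisible(x)
}

is_scan_geometry <- function(x) inherits(x, "scan_geometry")

#' Convert a pixel distance to micrometres
#'
#' @param n_px Non-negative pixel distance (may be fractional).
#' @param geometry A [scan_geometry()].
#' @return Length in um.
#' @examples
#' pixels_to_um(40)  # 480 um at the default 12 um/px
#' @export
pixels_to_um <- function(n_px, geometry = scan_geometry()) {
  stopifnot(is_scan_geometry(geometry))
  if (any(!is.finite(n_px)) || any(n_px < 0))
    stop("'n_px' must be finite and non-negative")
  n_px * geometry$pixel_size_um
}

#' Convert a visual angle to micrometres of retina
#'
#' Uses the angular calibration of the scan geometry (degrees per mm).
#' At the default 3.5 deg/mm, 2 degrees corresponds to about 571 um
#' (approximately 600 um).
#'
#' @param angle_deg Non-negative angle in degrees.
#' @inheritParams pixels_to_um
#' @return Length in um.
#' @examples
#' degrees_to_um(2)    # ~571.43
#' degrees_to_um(3.5)  # 1000
#' @export
degrees_to_um <- function(angle_deg, geometry = scan_geometry()) {
  stopifnot(is_scan_geometry(geometry))
  if (geometry$degrees_per_mm <= 0)
    stop("'degrees_per_mm' must be strictly positive")
  if (any(!is.finite(angle_deg)) || any(angle_deg < 0))
    stop("'angle_deg' must be finite and non-negative")
  angle_deg / geometry$degrees_per_mm * 1000
}

#' Convert micrometres to pixels
#'
#' @param um Non-negative length in micrometres.
#' @inheritParams pixels_to_um
#' @return Distance in (fractional) pixels.
#' @export
um_to_pixels <- function(um, geometry = scan_geometry()) {
  stopifnot(is_scan_geometry(geometry))
  if (any(!is.finite(um)) || any(um < 0))
    stop("'um' must be finite and non-negative")
  um / geometry$pixel_size_um
}
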