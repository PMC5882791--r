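#' Physical screen specification
#'
#' Describes the tablet display and working distance used by every geometric
#' conversion in the package. Degrees of visual angle are computed for a flat
#' screen viewed perpendicularly at `viewing_distance_mm`, so an offset of
#' `d` mm from the fixation point subtends `atan(d / distance)`.
#'
#' Defaults correspond to a 10-inch tablet (2560x1600 at 300 ppi) held at the
#' near-reading distance of 330 mm; all four values are configuration, not
#' constants, so any device profile can be supplied.
#'
#' @param width_px,height_px Screen resolution in pixels.
#' @param pixels_per_inch Physical pixel density (ppi).
#' @param viewing_distance_mm Eye-to-screen distance in millimetres.
#' @return An object of class `screen_spec`.
#' @examples
#' scr <- screen_spec()
#' scr$width_mm # 2560 * 25.4 / 300
#' @export
screen_spec <- function(width_px = 2560L, height_px = 1600L,
                        pixels_per_inch = 300, viewing_distance_mm = 330) {
  stopifnot(length(width_px) == 1, length(height_px) == 1,
            length(pixels_per_inch) == 1, length(viewing_distance_mm) == 1)
  if (width_px <= 0 || height_px <= 0 || pixels_per_inch <= 0 ||
      viewing_distance_mm <= 0) {
    stop("invalid screen configuration: all dimensions must be strictly positive",
         call. = FALSE)
  }
  structure(
    list(
      width_px = as.integer(width_px),
      height_px = as.integer(height_px),
      pixels_per_inch = pixels_per_inch,
      viewing_distance_mm = viewing_distance_mm,
      width_mm = width_px * 25.4 / pixels_per_inch,
      height_mm = height_px * 25.4 / pixels_per_inch
    ),
    class = "screen_spec"
  )
}

#' @export
print.screen_spec <- function(x, ...) {
  cat(sprintf("<screen_spec> %d x %d px @ %g ppi (%.1f x %.1f mm), viewed at %g mm\n",
              x$width_px, x$height_px, x$pixels_per_inch,
              x$width_mm, x$height_mm, x$viewing_distance_mm))
  invisible(x)
}

mm_per_px <- function(screen) 25.4 / screen$pixels_per_inch

#' Point in the visual field
#'
#' A position expressed in degrees of visual angle relative to the current
#' fixation point: `x_deg` positive rightward, `y_deg` positive upward
#' (patient-view coordinates). The polar fields follow the perimetric
#' convention: meridian 0 deg is the right horizontal, increasing
#' counter-clockwise.
#'
#' @param x_deg,y_deg Signed offsets from fixation in degrees.
#' @return An object of class `visual_point` with fields `x_deg`, `y_deg`,
#'   `eccentricity_deg` and `meridian_deg` (in `[0, 360)`).
#' @export
visual_point <- function(x_deg, y_deg) {
  ecc <- sqrt(x_deg^2 + y_deg^2)
  mer <- (atan2(y_deg, x_deg) * 180 / pi) %% 360
  structure(
    list(x_deg = x_deg, y_deg = y_deg,
         eccentricity_deg = ecc, meridian_deg = mer),
    class = "visual_point"
  )
}

#' Convert a screen pixel position to degrees of visual angle
#'
#' The pixel offset from the fixation anchor is converted to millimetres on
#' the panel and then to visual angle by the exact arctangent (no small-angle
#' approximation). Screen pixel coordinates have y increasing downward, so the
#' vertical offset is negated to obtain patient-view "up is positive".
#'
#' @param point_px,fixation_px Numeric length-2 vectors `(x, y)` in pixels.
#' @param screen A [screen_spec()].
#' @return A [visual_point()].
#' @examples
#' scr <- screen_spec()
#' px_to_deg(c(1380, 800), c(1280, 800), scr)
#' @export
px_to_deg <- function(point_px, fixation_px, screen) {
  stopifnot(inherits(screen, "screen_spec"),
            length(point_px) == 2, length(fixation_px) == 2)
  if (screen$viewing_distance_mm <= 0) {
    stop("invalid screen configuration: viewing distance must be positive",
         call. = FALSE)
  }
  dx_mm <- (point_px[1] - fixation_px[1]) * mm_per_px(screen)
  dy_mm <- -(point_px[2] - fixation_px[2]) * mm_per_px(screen)
  visual_point(
    x_deg = atan(dx_mm / screen$viewing_distance_mm) * 180 / pi,
    y_deg = atan(dy_mm / screen$viewing_distance_mm) * 180 / pi
  )
}

#' Angular diameter of a Goldmann-style stimulus
#'
#' A Goldmann perimetric stimulus is defined by its area at the bowl radius
#' (size III: 4 mm2 at 300 mm). Its angular diameter is that of the disc of
#' equal area: `2 * atan(sqrt(area / pi) / distance)`.
#'
#' @param area_mm2 Stimulus area in mm2 (size III default).
#' @param distance_mm Reference distance in mm (Goldmann bowl radius default).
#' @return Diameter in degrees of visual angle.
#' @examples
#' goldmann_equivalent_diameter_deg() # ~0.431 for size III
#' @export
goldmann_equivalent_diameter_deg <- function(area_mm2 = 4, distance_mm = 300) {
  if (any(distance_mm <= 0)) {
    stop("invalid configuration: distance must be strictly positive", call. = FALSE)
  }
  if (any(area_mm2 < 0)) stop("stimulus area must be non-negative", call. = FALSE)
  2 * atan(sqrt(area_mm2 / pi) / distance_mm) * 180 / pi
}

#' Render an angular diameter as a pixel count
#'
#' Converts a target diameter in degrees to the on-screen pixel diameter at
#' the screen's viewing distance, by the exact tangent. Any strictly positive
#' angular size maps to at least one pixel so a stimulus is never rendered
#' invisible by rounding.
#'
#' @param diameter_deg Angular diameter in degrees (>= 0).
#' @param screen A [screen_spec()].
#' @return Integer pixel diameter.
#' @examples
#' deg_to_px_size(goldmann_equivalent_diameter_deg(), screen_spec()) # 29 px
#' @export
deg_to_px_size <- function(diameter_deg, screen) {
  stopifnot(inherits(screen, "screen_spec"))
  if (diameter_deg < 0) stop("diameter must be non-negative", call. = FALSE)
  if (diameter_deg == 0) return(0L)
  size_mm <- 2 * screen$viewing_distance_mm * tan(diameter_deg / 2 * pi / 180)
  max(1L, as.integer(round(size_mm / mm_per_px(screen))))
}

#' Goldmann-III equivalent stimulus for a given screen
#'
#' Bundles the reference stimulus (area at the Goldmann bowl radius) with its
#' rendered size on the device: the rendered target matches the *angular*
#' subtense of the reference stimulus, not its physical size.
#'
#' @param screen A [screen_spec()].
#' @param area_mm2_at_reference Stimulus area at the reference distance.
#' @param reference_distance_mm Reference distance (Goldmann bowl radius).
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(screen, area_mm2_at_reference = 4,
                          reference_distance_mm = 300) {
  d_deg <- goldmann_equivalent_diameter_deg(area_mm2_at_reference,
                                            reference_distance_mm)
  structure(
    list(area_mm2_at_reference = area_mm2_at_reference,
         reference_distance_mm = reference_distance_mm,
         rendered_diameter_deg = d_deg,
         rendered_diameter_px = deg_to_px_size(d_deg, screen)),
    class = "stimulus_spec"
  )
}
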