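#' Simulate a field defect on a camera image
#'
#' Emulates the "see what the patient sees" view: the live camera image with
#' the binocular field defect painted over it. Pixels falling inside the
#' defect region — the homonymous defective quadrants from [classify_field()],
#' centred on the image centre, minus the spared central disc for the
#' macula-sparing variant — are replaced by the mean colour of that region;
#' all other pixels are untouched and the image dimensions are preserved.
#'
#' The image is mapped onto the visual field with the fixation point at the
#' image centre and the image half-width spanning the maximum tested
#' eccentricity; only the sparing disc depends on this scale (quadrant
#' membership is scale-free).
#'
#' @param image Numeric matrix (grey) or H x W x C array (colour), values on
#'   any scale.
#' @param left,right Gradable `field_map` objects for the two eyes.
#' @param config A [perimetry_config()].
#' @return A raster of the same dimensions and type.
#' @examples
#' # a normal field leaves the image untouched
#' @export
apply_field_filter <- function(image, left, right, config = perimetry_config()) {
  if (length(image) == 0) stop("empty image", call. = FALSE)
  cls <- classify_field(left, right, config)
  if (cls$grade == "non-gradable") {
    stop("field maps are non-gradable; refusing to build a defect filter",
         call. = FALSE)
  }
  dims <- dim(image)
  if (is.null(dims) || length(dims) < 2) stop("image must be a matrix or array",
                                              call. = FALSE)
  h <- dims[1]; w <- dims[2]
  nch <- if (length(dims) == 3) dims[3] else 1L

  homq <- cls$details$homonymous_quadrants
  if (!any(homq)) return(image)

  # pixel centres in field coordinates: x right, y up, fixation at centre
  xs <- matrix(rep(seq_len(w) - (w + 1) / 2, each = h), nrow = h)
  ys <- matrix(rep((h + 1) / 2 - seq_len(h), times = w), nrow = h)
  mer <- (atan2(ys, xs) * 180 / pi) %% 360
  quad <- matrix(meridian_quadrant(mer), nrow = h)
  in_defect <- matrix(homq[quad], nrow = h)

  if (!is.null(cls$subtype) && startsWith(cls$subtype, "macula-sparing")) {
    max_ext <- max(left$points$tested_extent_deg, right$points$tested_extent_deg)
    deg_per_unit <- max_ext / (w / 2)
    ecc <- sqrt(xs^2 + ys^2) * deg_per_unit
    in_defect <- in_defect & ecc > config$sparing_radius_deg
  }

  if (!any(in_defect)) return(image)

  out <- image
  if (nch == 1L) {
    out[in_defect] <- mean(image[in_defect])
  } else {
    for (ch in seq_len(nch)) {
      plane <- image[, , ch]
      plane[in_defect] <- mean(plane[in_defect])
      out[, , ch] <- plane
    }
  }
  out
}

#' Write a raster to PNG
#'
#' Convenience wrapper that rescales the raster to `[0, 1]` if needed and
#' writes it with the png package.
#'
#' @param image Numeric matrix or H x W x C array.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster_png <- function(image, path) {
  rng <- range(image)
  if (rng[1] < 0 || rng[2] > 1) {
    image <- (image - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  }
  png::writePNG(image, path)
  invisible(path)
}

#' Render a field map as a raster
#'
#' Greyscale polar rendering of the corrected isopter: a pixel is light when
#' its eccentricity lies inside the corrected boundary of the
#' nearest-in-angle tested meridian, dark outside it. Intended for report
#' attachments, not quantitative use.
#'
#' @param map A `field_map`.
#' @param size Output raster side length in pixels.
#' @return A `size` x `size` numeric matrix in `[0, 1]`.
#' @export
render_field_map <- function(map, size = 200L) {
  stopifnot(inherits(map, "field_map"))
  pts <- map$points
  max_ext <- max(pts$tested_extent_deg)
  xs <- matrix(rep(seq_len(size) - (size + 1) / 2, each = size), nrow = size)
  ys <- matrix(rep((size + 1) / 2 - seq_len(size), times = size), nrow = size)
  deg_per_unit <- max_ext / (size / 2)
  ecc <- sqrt(xs^2 + ys^2) * deg_per_unit
  mer <- (atan2(ys, xs) * 180 / pi) %% 360
  # nearest tested meridian by circular distance
  dmat <- outer(as.vector(mer), pts$meridian_deg,
                function(a, b) pmin(abs(a - b), 360 - abs(a - b)))
  nearest <- apply(dmat, 1, which.min)
  bound <- ifelse(pts$detected[nearest], pts$corrected_ecc_deg[nearest], 0)
  seen <- as.vector(ecc) <= bound
  matrix(ifelse(seen, 0.9, 0.2), nrow = size)
}
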