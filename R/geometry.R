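#' Measurement configuration
#'
#' Conventions for the landmark/measurement pipeline.
#'
#' @param anterior_side Which image side is anterior (the patient's front):
#'   `"right"` (default) or `"left"`. Radiograph laterality is acquisition-
#'   dependent, so it is a configuration, not an assumption. It fixes the
#'   sign of the sagittal vertical axis (positive = C3 anterior to the C7
#'   plumb line) and of the Cobb angle (positive = lordotic), and selects
#'   which horizontal band of the C7 contour holds its posterosuperior
#'   corner.
#' @param band_fraction Width of the horizontal contour bands used for
#'   endplate/corner detection, as a fraction of the contour's x-extent;
#'   must lie in (0, 0.5]. Default 0.25 (the leftmost/rightmost quarter).
#' @param contour_source `"polygon_direct"` (default; the contour is the
#'   annotation polygon itself — exact) or `"raster"` (polygon -> binary
#'   mask -> traced boundary, reproducing the raster pipeline at pixel
#'   resolution).
#' @param pixel_spacing Optional scale factor (length units per pixel)
#'   applied to all length outputs; default 1 (report pixels).
#' @return A `measurement_config` list.
#' @export
measurement_config <- function(anterior_side = c("right", "left"),
                               band_fraction = 0.25,
                               contour_source = c("polygon_direct", "raster"),
                               pixel_spacing = 1) {
  anterior_side <- match.arg(anterior_side)
  contour_source <- match.arg(contour_source)
  if (!is.numeric(band_fraction) || band_fraction <= 0 || band_fraction > 0.5)
    stop("band_fraction must lie in (0, 0.5]")
  if (pixel_spacing <= 0) stop("pixel_spacing must be positive")
  structure(list(anterior_side = anterior_side,
                 band_fraction = band_fraction,
                 contour_source = contour_source,
                 pixel_spacing = pixel_spacing),
            class = "measurement_config")
}

#' Extreme contour point within a horizontal band
#'
#' Sorts the contour by x to delimit the leftmost (or rightmost)
#' `band_fraction` of its x-extent, then returns the lowest (maximum y;
#' image y grows downward) or highest (minimum y) point inside that band.
#' Ties are broken by smaller x, then by smaller point index, so the
#' result is deterministic.
#'
#' @param contour n x 2 (x, y) point matrix (a traced `contour` or polygon
#'   vertices).
#' @param band `"leftmost"` or `"rightmost"`.
#' @param extreme `"lowest"` (max y) or `"highest"` (min y).
#' @param band_fraction Band width as a fraction of the x-extent, (0, 0.5].
#' @return Named numeric vector `c(x = , y = )`.
#' @export
band_extreme_point <- function(contour,
                               band = c("leftmost", "rightmost"),
                               extreme = c("lowest", "highest"),
                               band_fraction = 0.25) {
  band <- match.arg(band)
  extreme <- match.arg(extreme)
  pts <- as_polygon(contour)
  if (nrow(pts) < 3L) stop("contour must have at least 3 points")
  xr <- range(pts[, 1L])
  cut <- band_fraction * (xr[2L] - xr[1L])
  keep <- if (band == "leftmost") pts[, 1L] <= xr[1L] + cut
          else                    pts[, 1L] >= xr[2L] - cut
  if (!any(keep)) stop("empty contour band")  # degenerate contours only
  idx <- which(keep)
  y <- pts[idx, 2L]
  best_y <- if (extreme == "lowest") max(y) else min(y)
  cand <- idx[y == best_y]
  cand <- cand[pts[cand, 1L] == min(pts[cand, 1L])]
  p <- pts[min(cand), ]
  c(x = p[[1L]], y = p[[2L]])
}

#' Endplate line from band-extreme contour points
#'
#' The C3 inferior endplate joins the lowest contour points of the
#' leftmost and rightmost horizontal bands; the C7 superior endplate joins
#' the highest points of the two bands. (A tangent line needs two anchor
#' points; one band-extreme per side supplies them.)
#'
#' @param contour n x 2 point matrix.
#' @param kind `"c3_inferior"` or `"c7_superior"`.
#' @param cfg A [measurement_config()].
#' @return A `line_segment`: list with points `a` (left band) and `b`
#'   (right band).
#' @export
endplate_line <- function(contour, kind = c("c3_inferior", "c7_superior"),
                          cfg = measurement_config()) {
  kind <- match.arg(kind)
  extreme <- if (kind == "c3_inferior") "lowest" else "highest"
  a <- band_extreme_point(contour, "leftmost", extreme, cfg$band_fraction)
  b <- band_extreme_point(contour, "rightmost", extreme, cfg$band_fraction)
  if (all(abs(a - b) < 1e-12))
    stop("degenerate endplate: band extremes coincide")
  structure(list(a = a, b = b, kind = kind), class = "line_segment")
}

line_angle <- function(seg) {
  d <- seg$b - seg$a
  atan2(d[["y"]], d[["x"]])  # radians, screen coordinates (y down)
}

#' Cobb angle between two endplate lines
#'
#' Signed acute angle between the lines carrying segments `a` and `b`,
#' in degrees, normalized to (-90, 90]. With `a` the C3 inferior endplate
#' and `b` the C7 superior endplate, the sign convention (positive =
#' lordotic) is: angle = angle(b) - angle(a) in screen coordinates when
#' the anterior side is image-right, negated when anterior is image-left.
#'
#' @param a,b `line_segment` objects (or lists with points `a`, `b`).
#' @param cfg A [measurement_config()] (supplies `anterior_side`).
#' @return Angle in degrees, (-90, 90].
#' @export
cobb_angle <- function(a, b, cfg = measurement_config()) {
  ang <- (line_angle(b) - line_angle(a)) * 180 / pi
  # lines are undirected: reduce to (-90, 90]
  ang <- ((ang + 90) %% 180) - 90
  if (ang == -90) ang <- 90
  if (cfg$anterior_side == "left") ang <- -ang
  ang
}

#' Posterosuperior corner of the C7 vertebral body
#'
#' Highest contour point within the posterior horizontal band (the band on
#' the side opposite `cfg$anterior_side`); anchors the vertical plumb line
#' for the sagittal vertical axis.
#'
#' @param contour n x 2 point matrix of the C7 contour.
#' @param cfg A [measurement_config()].
#' @return Named numeric vector `c(x = , y = )`.
#' @export
posterosuperior_point <- function(contour, cfg = measurement_config()) {
  posterior_band <- if (cfg$anterior_side == "right") "leftmost" else "rightmost"
  band_extreme_point(contour, posterior_band, "highest", cfg$band_fraction)
}

#' Sagittal vertical axis (SVA) of C3
#'
#' Horizontal offset of the C3 centroid from the vertical plumb line
#' through the C7 posterosuperior corner; positive = anterior displacement.
#'
#' @param c3_centroid,c7_ps (x, y) points.
#' @param cfg A [measurement_config()].
#' @return Signed length (pixels times `pixel_spacing`).
#' @export
compute_sva <- function(c3_centroid, c7_ps, cfg = measurement_config()) {
  s <- if (cfg$anterior_side == "right") 1 else -1
  s * (c3_centroid[["x"]] - c7_ps[["x"]]) * cfg$pixel_spacing
}

#' Vertical length of the C3-C7 segment
#'
#' Absolute vertical displacement between the C3 and C7 centroids.
#'
#' @param c3,c7 Centroid points.
#' @param pixel_spacing Length units per pixel.
#' @return Non-negative length.
#' @export
compute_vertical_length <- function(c3, c7, pixel_spacing = 1) {
  abs(c3[["y"]] - c7[["y"]]) * pixel_spacing
}

#' Curved length of the C3-C7 segment
#'
#' Sum of Euclidean distances between consecutive vertebral centroids
#' (C3-C4-C5-C6-C7), approximating the cervical curvature. Always at least
#' the straight C3-C7 distance (triangle inequality), hence at least the
#' vertical length.
#'
#' @param centroids List or 5 x 2 matrix of centroids in C3..C7 order.
#' @param pixel_spacing Length units per pixel.
#' @return Non-negative length.
#' @export
compute_curved_length <- function(centroids, pixel_spacing = 1) {
  if (is.list(centroids)) centroids <- do.call(rbind, centroids)
  if (nrow(centroids) != 5L)
    stop("missing vertebra: need the 5 centroids C3..C7, got ",
         nrow(centroids))
  d <- diff(centroids)
  sum(sqrt(rowSums(d^2))) * pixel_spacing
}

vertebra_contour <- function(a, label, cfg) {
  poly <- a$vertebrae[[label]]
  if (cfg$contour_source == "polygon_direct") return(poly)
  m <- rasterize_polygon(poly, a$width, a$height)
  extract_contour(m)
}

#' Measure the four sagittal alignment parameters of one radiograph
#'
#' Composes the landmark operations: polygon centroids of C3-C7, the C3
#' inferior and C7 superior endplate lines, and the C7 posterosuperior
#' corner, yielding SVA, C3-C7 lordosis (Cobb angle), vertical length, and
#' curved length. In `"raster"` mode the centroid and the landmark points
#' are taken from the traced mask boundary rather than the polygon, which
#' reproduces the pixel-level pipeline at ~1 px accuracy.
#'
#' @param a A valid `radiograph_annotation` ([validate_annotation()] must
#'   return no issues).
#' @param cfg A [measurement_config()].
#' @return List with `landmarks` (centroids, endplate segments,
#'   posterosuperior point) and `parameters`, an `alignment_parameters`
#'   object with fields `sva`, `lordosis_deg`, `vertical_length`,
#'   `curved_length`.
#' @examples
#' gen <- generate_spine_annotation(spine_geometry_config(
#'   lordosis_deg = 24.1, sva = 70.6))
#' measure_radiograph(gen$annotation)$parameters
#' @export
measure_radiograph <- function(a, cfg = measurement_config()) {
  issues <- validate_annotation(a)
  if (length(issues))
    stop("annotation '", a$image_id, "' is not measurable: ",
         paste(issues, collapse = ", "))
  contours <- lapply(CERVICAL_LABELS, function(lab)
    tryCatch(vertebra_contour(a, lab, cfg),
             error = function(e) stop(lab, ": ", conditionMessage(e),
                                      call. = FALSE)))
  names(contours) <- CERVICAL_LABELS
  centroids <- lapply(contours, polygon_centroid)
  c3_inf <- endplate_line(contours$C3, "c3_inferior", cfg)
  c7_sup <- endplate_line(contours$C7, "c7_superior", cfg)
  c7_ps <- posterosuperior_point(contours$C7, cfg)
  params <- alignment_parameters(
    sva = compute_sva(centroids$C3, c7_ps, cfg),
    lordosis_deg = cobb_angle(c3_inf, c7_sup, cfg),
    vertical_length = compute_vertical_length(centroids$C3, centroids$C7,
                                              cfg$pixel_spacing),
    curved_length = compute_curved_length(centroids, cfg$pixel_spacing))
  landmarks <- list(centroids = centroids, c3_inferior_endplate = c3_inf,
                    c7_superior_endplate = c7_sup, c7_posterosuperior = c7_ps)
  list(landmarks = landmarks, parameters = params)
}

#' Alignment parameter record
#'
#' @param sva Signed sagittal vertical axis (positive = anterior).
#' @param lordosis_deg Signed C3-C7 Cobb angle, degrees (positive =
#'   lordotic). Values beyond +/-90 are anatomically impossible; |value| >
#'   90 cannot occur by construction, but |value| close to 90 triggers a
#'   warning.
#' @param vertical_length,curved_length Non-negative lengths; the curved
#'   length can never be smaller than the vertical length.
#' @return An `alignment_parameters` list.
#' @export
alignment_parameters <- function(sva, lordosis_deg, vertical_length,
                                 curved_length) {
  if (vertical_length < 0 || curved_length < 0)
    stop("lengths must be non-negative")
  if (curved_length < vertical_length - 1e-9)
    stop("curved_length cannot be smaller than vertical_length")
  if (abs(lordosis_deg) > 85)
    warning("lordosis of ", round(lordosis_deg, 1),
            " degrees is outside the plausible anatomical range")
  structure(list(sva = sva, lordosis_deg = lordosis_deg,
                 vertical_length = vertical_length,
                 curved_length = curved_length),
            class = "alignment_parameters")
}

#' @export
print.alignment_parameters <- function(x, ...) {
  cat(sprintf(paste0("<alignment_parameters> sva=%.2f lordosis=%.2f deg ",
                     "vertical=%.2f curved=%.2f\n"),
              x$sva, x$lordosis_deg, x$vertical_length, x$curved_length))
  invisible(x)
}

#' @export
as.data.frame.alignment_parameters <- function(x, ...) {
  data.frame(sva = x$sva, lordosis_deg = x$lordosis_deg,
             vertical_length = x$vertical_length,
             curved_length = x$curved_length)
}
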