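#' Spine geometry configuration for the synthetic annotation generator
#'
#' Describes a synthetic lateral-radiograph annotation: five rectangular
#' C3-C7 vertebral bodies placed along an arc. Rectangles (rather than
#' anatomical silhouettes) keep every landmark — corners, endplate lines,
#' centroids — exact, so the measurement operators can be validated against
#' closed-form ground truth.
#'
#' @param lordosis_deg Target C3-C7 Cobb angle in degrees (|value| < 90).
#'   Consecutive body orientations differ by `lordosis_deg / 4`, so the C3
#'   inferior and C7 superior endplates subtend exactly this angle.
#' @param sva Target sagittal vertical axis in pixels (positive =
#'   anterior); achieved exactly by a uniform horizontal shear of the body
#'   centers.
#' @param segment_gap Distance between consecutive body centers, pixels.
#' @param body_width,body_height Rectangle dimensions, pixels.
#' @param image_width,image_height Frame dimensions, pixels.
#' @param anterior_side `"right"` (default) or `"left"`; with `"left"` the
#'   construction is mirrored horizontally.
#' @param margin Minimum distance from any vertex to the frame border.
#' @param jitter_px Optional uniform vertex jitter amplitude (pixels);
#'   breaks exactness, so ground truth refers to the unjittered
#'   construction. Default 0.
#' @param seed RNG seed used only when `jitter_px > 0`.
#' @return A `spine_geometry_config` list.
#' @export
spine_geometry_config <- function(lordosis_deg = 13.9, sva = 95.9,
                                  segment_gap = 115, body_width = 60,
                                  body_height = 40, image_width = 1000,
                                  image_height = 1400,
                                  anterior_side = c("right", "left"),
                                  margin = 30, jitter_px = 0, seed = 0L) {
  anterior_side <- match.arg(anterior_side)
  if (abs(lordosis_deg) >= 90) stop("|lordosis_deg| must be below 90")
  if (min(segment_gap, body_width, body_height, image_width, image_height)
      <= 0)
    stop("all dimensions must be positive")
  structure(list(lordosis_deg = lordosis_deg, sva = sva,
                 segment_gap = segment_gap, body_width = body_width,
                 body_height = body_height, image_width = image_width,
                 image_height = image_height, anterior_side = anterior_side,
                 margin = margin, jitter_px = jitter_px, seed = seed),
            class = "spine_geometry_config")
}

# Body tilts for a target Cobb angle: C3 at -L/2 ... C7 at +L/2 (radians),
# evenly spaced, so the C3 inferior / C7 superior endplates subtend L and
# consecutive bodies differ by L/4.
spine_tilts <- function(lordosis_deg) {
  L <- lordosis_deg * pi / 180
  -L / 2 + (0:4) * L / 4
}

# Rotated-rectangle corners around a center: top-left, top-right,
# bottom-right, bottom-left in screen terms at tilt 0. Local u = anterior
# (+x), v = inferior (+y); world = center + (u cos t - v sin t,
# u sin t + v cos t).
body_corners <- function(center, w, h, tilt) {
  u <- c(-w, w, w, -w) / 2
  v <- c(-h, -h, h, h) / 2
  cbind(x = center[1L] + u * cos(tilt) - v * sin(tilt),
        y = center[2L] + u * sin(tilt) + v * cos(tilt))
}

# x-offset of the posterosuperior (top-left at anterior = right) corner of
# C7 from its center.
ps_corner_offset <- function(w, h, tilt)
  -w / 2 * cos(tilt) + h / 2 * sin(tilt)

# Assemble the annotation from explicit step vectors (a = horizontal,
# b = vertical, both length 4) and per-body tilts; shared by the direct
# generator and the cohort generator.
build_spine <- function(cfg, tilts, a, b, image_id = "synthetic-spine") {
  centers <- rbind(c(0, 0), cbind(cumsum(a), cumsum(b)))
  polys <- lapply(1:5, function(i)
    body_corners(centers[i, ], cfg$body_width, cfg$body_height, tilts[i]))
  all_xy <- do.call(rbind, polys)
  if (cfg$jitter_px > 0) {
    polys <- withr::with_seed(cfg$seed, lapply(polys, function(p)
      p + matrix(stats::runif(8, -cfg$jitter_px, cfg$jitter_px), ncol = 2)))
    all_xy <- do.call(rbind, polys)
  }
  shift <- c(cfg$margin - min(all_xy[, 1L]), cfg$margin - min(all_xy[, 2L]))
  polys <- lapply(polys, function(p) sweep(p, 2L, -shift))
  centers <- sweep(centers, 2L, -shift)
  ext <- apply(do.call(rbind, polys), 2L, max)
  if (ext[1L] > cfg$image_width - cfg$margin ||
      ext[2L] > cfg$image_height - cfg$margin)
    stop("configured spine does not fit in the image frame (needs ",
         ceiling(ext[1L] + cfg$margin), " x ", ceiling(ext[2L] + cfg$margin),
         " px)")
  mirror <- identity
  if (cfg$anterior_side == "left")
    mirror <- function(p) {
      p[, 1L] <- cfg$image_width - p[, 1L]
      p
    }
  polys <- lapply(polys, mirror)
  centers <- mirror(centers)
  names(polys) <- CERVICAL_LABELS
  ann <- radiograph_annotation(image_id, cfg$image_width, cfg$image_height,
                               polys)
  c7_sup <- polys$C7[1:2, , drop = FALSE]  # top-left, top-right corners
  ps_idx <- if (cfg$anterior_side == "right") 1L else 2L
  rownames(centers) <- CERVICAL_LABELS
  list(annotation = ann,
       centroids = centers,
       c7_superior_corners = c7_sup,
       c7_posterosuperior = c(x = unname(c7_sup[ps_idx, 1L]),
                              y = unname(c7_sup[ps_idx, 2L])))
}

#' Generate a synthetic spine annotation with analytic ground truth
#'
#' Places five rectangular vertebral bodies along an arc whose endplate
#' tilts realize the configured lordosis exactly, then shears the body
#' centers horizontally so the configured SVA is met exactly. Vertical and
#' curved lengths follow in closed form from the construction. Measuring
#' the result with [measure_radiograph()] in `polygon_direct` mode
#' recovers the ground truth to machine precision.
#'
#' @param cfg A [spine_geometry_config()].
#' @return List with `annotation` (a `radiograph_annotation`), `truth`
#'   (an `alignment_parameters` with the analytic values), and `landmarks`
#'   (ground-truth centroids, C7 superior corners, and posterosuperior
#'   corner).
#' @export
generate_spine_annotation <- function(cfg = spine_geometry_config()) {
  stopifnot(inherits(cfg, "spine_geometry_config"))
  tilts <- spine_tilts(cfg$lordosis_deg)
  phi <- (tilts[-5L] + tilts[-1L]) / 2     # inter-centroid step tilts
  g <- cfg$segment_gap
  b <- g * cos(phi)
  xps <- ps_corner_offset(cfg$body_width, cfg$body_height, tilts[5L])
  A <- -(cfg$sva + xps)                    # required total horizontal drift
  a <- g * sin(phi) + (A - sum(g * sin(phi))) / 4
  built <- build_spine(cfg, tilts, a, b)
  truth <- alignment_parameters(
    sva = cfg$sva, lordosis_deg = cfg$lordosis_deg,
    vertical_length = sum(b), curved_length = sum(sqrt(a^2 + b^2)))
  list(annotation = built$annotation, truth = truth,
       landmarks = built[c("centroids", "c7_superior_corners",
                           "c7_posterosuperior")])
}

# Given target (sva, lordosis, vertical, curved), solve for step vectors
# whose construction realizes the tuple exactly: equal vertical steps V/4,
# horizontal steps A/4 +/- e with alternating signs (sum preserved), e
# chosen so the chord sum equals the curved length.
solve_spine_steps <- function(cfg, lordosis_deg, sva, vertical, curved) {
  tilts <- spine_tilts(lordosis_deg)
  xps <- ps_corner_offset(cfg$body_width, cfg$body_height, tilts[5L])
  A <- -(sva + xps)
  b <- rep(vertical / 4, 4L)
  chord <- sqrt(A^2 + vertical^2)
  if (curved < chord - 1e-9)
    stop("infeasible parameters: curved length ", round(curved, 2),
         " below the straight C3-C7 distance ", round(chord, 2))
  f <- function(e) {
    a <- A / 4 + e * c(1, -1, 1, -1)
    sum(sqrt(a^2 + b^2)) - curved
  }
  e <- if (f(0) >= -1e-9) 0 else
    stats::uniroot(f, c(0, abs(A) + curved), tol = 1e-12)$root
  list(tilts = tilts, a = A / 4 + e * c(1, -1, 1, -1), b = b)
}

#' Generate a cohort of spine annotations matching sampled parameters
#'
#' For each sampled parameter tuple (sva, lordosis, vertical length,
#' curved length) constructs one spine annotation whose analytic ground
#' truth equals the tuple, enabling full-pipeline closure tests
#' (measurement recovers the sampled parameters).
#'
#' @param parameters Data frame with columns `sva`, `lordosis_deg`,
#'   `vertical_length`, `curved_length` (e.g. from [simulate_cohort()]).
#' @param template A [spine_geometry_config()] supplying body dimensions,
#'   frame size and conventions.
#' @param path Optional path; when given, the annotations are also written
#'   as native JSON via [write_annotations()].
#' @return List with `annotations` (list of `radiograph_annotation`) and
#'   `truth` (the input data frame with an `image_id` column prepended).
#' @export
generate_cohort_annotations <- function(parameters,
                                        template = spine_geometry_config(),
                                        path = NULL) {
  need <- c("sva", "lordosis_deg", "vertical_length", "curved_length")
  if (!all(need %in% names(parameters)))
    stop("parameters must have columns: ", paste(need, collapse = ", "))
  anns <- vector("list", nrow(parameters))
  ids <- sprintf("synthetic-%04d", seq_len(nrow(parameters)))
  for (r in seq_len(nrow(parameters))) {
    st <- solve_spine_steps(template, parameters$lordosis_deg[r],
                            parameters$sva[r], parameters$vertical_length[r],
                            parameters$curved_length[r])
    anns[[r]] <- build_spine(template, st$tilts, st$a, st$b,
                             image_id = ids[r])$annotation
  }
  truth <- cbind(image_id = ids, parameters[, need])
  if (!is.null(path)) write_annotations(anns, path)
  list(annotations = anns, truth = truth)
}
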