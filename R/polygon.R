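#' Polygon primitives
#'
#' Small, dependency-free geometry helpers used throughout the measurement
#' pipeline. Polygons are n x 2 numeric matrices with columns `x`, `y`
#' (image convention: x rightward, y downward, 0-based pixel coordinates),
#' listing vertices in order without repeating the first vertex.
#'
#' @name polygon-primitives
#' @keywords internal
NULL

as_polygon <- function(p) {
  p <- as.matrix(p)
  if (!is.numeric(p) || ncol(p) != 2L)
    stop("polygon must be an n x 2 numeric matrix of (x, y) vertices")
  if (nrow(p) >= 2L && isTRUE(all.equal(p[1L, ], p[nrow(p), ])))
    p <- p[-nrow(p), , drop = FALSE]  # drop explicit closure
  colnames(p) <- c("x", "y")
  if (anyNA(p) || any(!is.finite(p))) stop("polygon vertices must be finite")
  p
}

#' Signed area of a simple polygon (shoelace formula)
#' @param p n x 2 vertex matrix.
#' @return Signed area; positive for counter-clockwise vertex order in a
#'   y-down coordinate system the sign is flipped relative to math plots,
#'   which is why callers use `abs()`.
#' @keywords internal
polygon_area_signed <- function(p) {
  p <- as_polygon(p)
  n <- nrow(p)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  sum(p[, 1L] * p[j, 2L] - p[j, 1L] * p[, 2L]) / 2
}

#' Area-weighted centroid of a simple polygon
#'
#' The shoelace-based centroid: with vertices \eqn{(x_i, y_i)} and cross
#' terms \eqn{c_i = x_i y_{i+1} - x_{i+1} y_i},
#' \eqn{C_x = \sum (x_i + x_{i+1}) c_i / (6A)} and likewise for
#' \eqn{C_y}. Orientation-independent.
#'
#' @param p An n x 2 matrix (n >= 3) of polygon vertices, or anything
#'   coercible to one.
#' @return Named numeric vector `c(x = , y = )`.
#' @examples
#' polygon_centroid(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # (0.5, 0.5)
#' @export
polygon_centroid <- function(p) {
  p <- as_polygon(p)
  a <- polygon_area_signed(p)
  if (abs(a) < .Machine$double.eps * 100)
    stop("degenerate polygon: zero enclosed area")
  n <- nrow(p)
  j <- c(2:n, 1L)
  cross <- p[, 1L] * p[j, 2L] - p[j, 1L] * p[, 2L]
  cx <- sum((p[, 1L] + p[j, 1L]) * cross) / (6 * a)
  cy <- sum((p[, 2L] + p[j, 2L]) * cross) / (6 * a)
  c(x = cx, y = cy)
}

# Proper/improper intersection test between segments p1-p2 and p3-p4.
# Collinear overlapping segments count as intersecting.
segments_intersect <- function(p1, p2, p3, p4, eps = 1e-12) {
  d1 <- cross2(p4 - p3, p1 - p3)
  d2 <- cross2(p4 - p3, p2 - p3)
  d3 <- cross2(p2 - p1, p3 - p1)
  d4 <- cross2(p2 - p1, p4 - p1)
  if (((d1 > eps && d2 < -eps) || (d1 < -eps && d2 > eps)) &&
      ((d3 > eps && d4 < -eps) || (d3 < -eps && d4 > eps))) return(TRUE)
  on_seg <- function(a, b, c) {  # c collinear with a-b: does it lie on it?
    min(a[1], b[1]) - eps <= c[1] && c[1] <= max(a[1], b[1]) + eps &&
    min(a[2], b[2]) - eps <= c[2] && c[2] <= max(a[2], b[2]) + eps
  }
  (abs(d1) <= eps && on_seg(p3, p4, p1)) ||
  (abs(d2) <= eps && on_seg(p3, p4, p2)) ||
  (abs(d3) <= eps && on_seg(p1, p2, p3)) ||
  (abs(d4) <= eps && on_seg(p1, p2, p4))
}

cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]

#' Is a polygon simple (non-self-intersecting)?
#'
#' Pairwise segment-intersection test over all non-adjacent edge pairs;
#' adjacent edges may share only their common endpoint.
#'
#' @param p n x 2 vertex matrix.
#' @return `TRUE` or `FALSE`.
#' @export
is_simple_polygon <- function(p) {
  p <- as_polygon(p)
  n <- nrow(p)
  if (n < 3L) return(FALSE)
  if (anyDuplicated(p)) return(FALSE)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      if (k <= i) next
      # adjacent edges (share a vertex) are allowed to touch there
      if (k == i + 1L || (i == 1L && k == n)) next
      a1 <- p[i, ]; a2 <- p[if (i == n) 1L else i + 1L, ]
      b1 <- p[k, ]; b2 <- p[if (k == n) 1L else k + 1L, ]
      if (segments_intersect(a1, a2, b1, b2)) return(FALSE)
    }
  }
  TRUE
}

# Even-odd point-in-polygon for a batch of query points; points exactly on
# the boundary count as inside (the rasterizer's tie rule).
points_in_polygon <- function(px, py, poly, eps = 1e-9) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  j <- c(2:n, 1L)
  x1 <- poly[, 1L]; y1 <- poly[, 2L]
  x2 <- poly[j, 1L]; y2 <- poly[j, 2L]
  inside <- logical(length(px))
  boundary <- logical(length(px))
  for (e in seq_len(n)) {
    # ray casting: horizontal ray toward +x, half-open rule in y
    crosses <- ((y1[e] > py) != (y2[e] > py))
    if (any(crosses)) {
      xint <- x1[e] + (py[crosses] - y1[e]) * (x2[e] - x1[e]) / (y2[e] - y1[e])
      flip <- px[crosses] < xint - eps
      inside[crosses] <- xor(inside[crosses], flip)
      boundary[which(crosses)[abs(px[crosses] - xint) <= eps]] <- TRUE
    }
    # on-segment test (covers horizontal edges the ray rule skips)
    dx <- x2[e] - x1[e]; dy <- y2[e] - y1[e]
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- ((px - x1[e]) * dx + (py - y1[e]) * dy) / len2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (px - (x1[e] + t * dx))^2 + (py - (y1[e] + t * dy))^2
      boundary[d2 <= eps^2] <- TRUE
    }
  }
  inside | boundary
}
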