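#' Rasterize a polygon to a binary mask
#'
#' Pixel model: the image is a `width` x `height` grid of unit cells; cell
#' `(i, j)` (0-based, `i` along x, `j` along y) is foreground iff its
#' center `(i + 0.5, j + 0.5)` lies inside the polygon under the even-odd
#' rule, with points exactly on the polygon boundary counting as inside.
#' This makes the mask deterministic and checkable against a brute-force
#' point-in-polygon oracle.
#'
#' @param p Polygon (n x 2 vertex matrix), image pixel coordinates.
#' @param width,height Frame dimensions in pixels.
#' @return A `binary_mask`: list with `width`, `height`, and `fg`, a
#'   `height` x `width` logical matrix (row `j + 1`, column `i + 1`).
#' @export
rasterize_polygon <- function(p, width, height) {
  p <- as_polygon(p)
  if (width <= 0 || height <= 0) stop("mask dimensions must be positive")
  if (nrow(p) < 3L || abs(polygon_area_signed(p)) < 1e-12)
    stop("cannot rasterize a degenerate (zero-area) polygon")
  fg <- matrix(FALSE, nrow = height, ncol = width)
  # only pixel centers inside the bounding box can be foreground
  i0 <- max(0L, floor(min(p[, 1]) - 1)); i1 <- min(width  - 1L, ceiling(max(p[, 1])))
  j0 <- max(0L, floor(min(p[, 2]) - 1)); j1 <- min(height - 1L, ceiling(max(p[, 2])))
  if (i0 > i1 || j0 > j1) stop("polygon lies fully outside the image frame")
  ii <- i0:i1; jj <- j0:j1
  grid <- expand.grid(i = ii, j = jj)
  inside <- points_in_polygon(grid$i + 0.5, grid$j + 0.5, p)
  if (!any(inside)) stop("polygon lies fully outside the image frame ",
                         "(no pixel center covered)")
  fg[cbind(grid$j[inside] + 1L, grid$i[inside] + 1L)] <- TRUE
  structure(list(width = as.integer(width), height = as.integer(height),
                 fg = fg), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", x$width, " x ", x$height, " px, ",
      sum(x$fg), " foreground\n", sep = "")
  invisible(x)
}

mask_cells <- function(m) {
  w <- which(m$fg, arr.ind = TRUE)
  cbind(i = w[, "col"] - 1L, j = w[, "row"] - 1L)  # 0-based (x, y) cells
}

# 8-connected component count via flood fill over linear cell indices.
count_components <- function(m) {
  h <- m$height; w <- m$width
  fg <- m$fg
  seen <- matrix(FALSE, h, w)
  idx <- which(fg)
  if (!length(idx)) return(0L)
  nbr_dr <- rep(-1:1, 3L); nbr_dc <- rep(-1:1, each = 3L)
  ncomp <- 0L
  for (s in idx) {
    if (seen[s]) next
    ncomp <- ncomp + 1L
    stack <- integer(length(idx)); stack[1L] <- s; top <- 1L
    seen[s] <- TRUE
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      r0 <- (cur - 1L) %% h + 1L
      c0 <- (cur - 1L) %/% h + 1L
      rr <- r0 + nbr_dr; cc <- c0 + nbr_dc
      ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
      lin <- (cc[ok] - 1L) * h + rr[ok]
      lin <- lin[fg[lin] & !seen[lin]]
      if (length(lin)) {
        seen[lin] <- TRUE
        stack[(top + 1L):(top + length(lin))] <- lin
        top <- top + length(lin)
      }
    }
  }
  ncomp
}

# Moore neighborhood, clockwise on screen (y down), starting East.
MOORE <- cbind(dx = c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L),
               dy = c(0L, 1L, 1L,  1L,  0L, -1L, -1L, -1L))

#' Extract the closed boundary contour of a binary mask
#'
#' Moore-neighbor boundary tracing of the single 8-connected foreground
#' component, started at its topmost-then-leftmost pixel and walked
#' clockwise. Every contour point is a foreground boundary pixel; the
#' returned coordinates are pixel centers (`cell + 0.5`).
#'
#' @param m A `binary_mask` with exactly one connected component.
#' @return A `contour`: ordered n x 2 matrix of (x, y) pixel-center
#'   coordinates, closed implicitly (last point connects to first). A
#'   single-pixel mask yields a 1-point contour with attribute
#'   `degenerate = TRUE` and a warning.
#' @export
extract_contour <- function(m) {
  stopifnot(inherits(m, "binary_mask"))
  cells <- mask_cells(m)
  if (nrow(cells) == 0L) stop("cannot trace an empty mask")
  ncomp <- count_components(m)
  if (ncomp > 1L)
    stop("ambiguous mask: ", ncomp, " connected components (expected 1)")
  # start pixel: topmost row, then leftmost column
  ord <- order(cells[, "j"], cells[, "i"])
  start <- cells[ord[1L], ]
  fg_at <- function(i, j) i >= 0L && i < m$width && j >= 0L && j < m$height &&
    m$fg[j + 1L, i + 1L]
  start <- unname(start)
  if (nrow(cells) == 1L) {
    warning("single-pixel mask: degenerate 1-point contour")
    out <- matrix(start + 0.5, ncol = 2L, dimnames = list(NULL, c("x", "y")))
    return(structure(out, degenerate = TRUE, class = c("contour", "matrix")))
  }
  dir_index <- function(delta)
    which(MOORE[, "dx"] == delta[1L] & MOORE[, "dy"] == delta[2L])
  # by the scan order the cell west of the start pixel is background
  b0 <- start + c(-1L, 0L)
  p <- start; b <- b0
  path <- list(start)
  max_iter <- 4L * nrow(cells) + 8L
  repeat {
    d0 <- dir_index(b - p)
    advanced <- FALSE
    for (step in 1:8) {
      d <- (d0 + step - 1L) %% 8L + 1L  # clockwise, starting after backtrack
      cand <- p + unname(MOORE[d, ])
      if (fg_at(cand[1L], cand[2L])) {
        b <- p + unname(MOORE[(d - 2L) %% 8L + 1L, ])  # last background seen
        p <- cand
        advanced <- TRUE
        break
      }
    }
    if (!advanced) break                     # defensive; single pixel only
    if (all(p == start) && all(b == b0)) break  # Jacob's stopping criterion
    path[[length(path) + 1L]] <- p
    if (length(path) > max_iter) stop("contour tracing failed to close")
  }
  cells_path <- do.call(rbind, path)
  out <- cells_path + 0.5
  colnames(out) <- c("x", "y")
  structure(unique(out), class = c("contour", "matrix"))
}

#' @export
print.contour <- function(x, ...) {
  cat("<contour> ", nrow(x), " boundary points\n", sep = "")
  invisible(x)
}
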