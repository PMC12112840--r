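# Independent brute-force oracles. These deliberately use different
# algorithms from the package implementations they check.

# Winding-number point-in-polygon (angle summation); the implementation
# uses even-odd ray casting. Equivalent for simple polygons, for points
# not exactly on the boundary.
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  vapply(seq_along(px), function(q) {
    dx <- poly[, 1] - px[q]
    dy <- poly[, 2] - py[q]
    ang <- atan2(dy, dx)
    total <- sum(vapply(seq_len(n), function(i) {
      d <- ang[if (i == n) 1L else i + 1L] - ang[i]
      if (d > pi) d <- d - 2 * pi
      if (d < -pi) d <- d + 2 * pi
      d
    }, numeric(1)))
    abs(total) > pi  # ~2*pi inside, ~0 outside
  }, logical(1))
}

# Foreground cells (0-based i, j) of a mask that touch background or the
# frame border: the boundary-cell enumeration oracle. A Moore trace visits
# every cell with a background 4-neighbor and at most the cells with a
# background 8-neighbor (diagonal-only contact can be cut across), so the
# two connectivities bracket the traced set.
oracle_boundary_cells <- function(m, connectivity = 8) {
  offsets <- if (connectivity == 8)
    cbind(dj = rep(-1:1, 3), di = rep(-1:1, each = 3))
  else cbind(dj = c(-1, 1, 0, 0), di = c(0, 0, -1, 1))
  cells <- which(m$fg, arr.ind = TRUE)
  keep <- vapply(seq_len(nrow(cells)), function(r) {
    j <- cells[r, 1]; i <- cells[r, 2]  # row, col (1-based)
    for (o in seq_len(nrow(offsets))) {
      jj <- j + offsets[o, "dj"]; ii <- i + offsets[o, "di"]
      if (jj < 1 || jj > m$height || ii < 1 || ii > m$width) return(TRUE)
      if (!m$fg[jj, ii]) return(TRUE)
    }
    FALSE
  }, logical(1))
  cbind(i = cells[keep, 2] - 1L, j = cells[keep, 1] - 1L)
}

# Distance from a point to a polygon's boundary (min over edges).
dist_point_polygon <- function(p, poly) {
  n <- nrow(poly)
  min(vapply(seq_len(n), function(i) {
    a <- poly[i, ]; b <- poly[if (i == n) 1L else i + 1L, ]
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    sqrt(sum((p - (a + t * ab))^2))
  }, numeric(1)))
}

# Per-definition silhouette, plain double loops.
oracle_silhouette <- function(F, labels) {
  n <- nrow(F)
  d <- function(i, j) sqrt(sum((F[i, ] - F[j, ])^2))
  mean(vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1L) return(0)
    a <- mean(vapply(setdiff(which(own), i), function(j) d(i, j), numeric(1)))
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(vapply(which(labels == cl), function(j) d(i, j), numeric(1))),
      numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1)))
}

oracle_calinski_harabasz <- function(F, labels) {
  ks <- unique(labels); k <- length(ks); n <- nrow(F)
  grand <- colMeans(F)
  trB <- 0; trW <- 0
  for (cl in ks) {
    rows <- F[labels == cl, , drop = FALSE]
    ctr <- colMeans(rows)
    trB <- trB + nrow(rows) * sum((ctr - grand)^2)
    for (r in seq_len(nrow(rows))) trW <- trW + sum((rows[r, ] - ctr)^2)
  }
  (trB / (k - 1)) / (trW / (n - k))
}

oracle_davies_bouldin <- function(F, labels) {
  ks <- sort(unique(labels)); k <- length(ks)
  ctr <- lapply(ks, function(cl) colMeans(F[labels == cl, , drop = FALSE]))
  s <- vapply(seq_len(k), function(i) {
    rows <- F[labels == ks[i], , drop = FALSE]
    mean(vapply(seq_len(nrow(rows)), function(r)
      sqrt(sum((rows[r, ] - ctr[[i]])^2)), numeric(1)))
  }, numeric(1))
  mean(vapply(seq_len(k), function(i)
    max(vapply(setdiff(seq_len(k), i), function(j)
      (s[i] + s[j]) / sqrt(sum((ctr[[i]] - ctr[[j]])^2)), numeric(1))),
    numeric(1)))
}

oracle_wcss <- function(F, labels) {
  tot <- 0
  for (cl in unique(labels)) {
    rows <- F[labels == cl, , drop = FALSE]
    ctr <- colMeans(rows)
    for (r in seq_len(nrow(rows))) tot <- tot + sum((rows[r, ] - ctr)^2)
  }
  tot
}

# Globally optimal WCSS by exhaustive enumeration of all assignments of n
# points to k non-empty clusters (feasible for n <= 8).
oracle_kmeans_optimum <- function(F, k) {
  n <- nrow(F)
  stopifnot(n <= 8L)
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    lab <- as.integer(grid[r, ])
    if (length(unique(lab)) < k) next
    best <- min(best, oracle_wcss(F, lab))
  }
  best
}

# Textbook one-way ANOVA decomposition, written out longhand.
oracle_anova <- function(values, labels) {
  ks <- unique(labels); k <- length(ks); n <- length(values)
  grand <- mean(values)
  ssb <- sum(vapply(ks, function(cl)
    sum(labels == cl) * (mean(values[labels == cl]) - grand)^2, numeric(1)))
  ssw <- sum(vapply(ks, function(cl)
    sum((values[labels == cl] - mean(values[labels == cl]))^2), numeric(1)))
  F <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = F, p = pf(F, k - 1, n - k, lower.tail = FALSE))
}

# A small, fully valid hand-built annotation: five level rectangles.
make_level_annotation <- function(id = "test", width = 400, height = 700) {
  rect <- function(cx, cy, w = 60, h = 40)
    rbind(c(cx - w / 2, cy - h / 2), c(cx + w / 2, cy - h / 2),
          c(cx + w / 2, cy + h / 2), c(cx - w / 2, cy + h / 2))
  vert <- lapply(0:4, function(i) rect(200, 100 + i * 120))
  names(vert) <- c("C3", "C4", "C5", "C6", "C7")
  radiograph_annotation(id, width, height, vert)
}
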