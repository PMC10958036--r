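# Exact polygon geometry for patch coverage.
#
# Coverage of a patch by a set of (possibly overlapping) simple polygons
# is computed exactly with a y-slab scanline: between two consecutive
# "event" y-coordinates (polygon vertices and pairwise edge crossings)
# no edges cross, so the union of the x-intervals cut by a horizontal
# line has constant combinatorial structure and linearly moving
# endpoints; its length at the slab midline times the slab height is the
# exact area contribution.

#' Normalize a polygon ring
#'
#' Drops an explicit closing vertex and consecutive duplicate vertices.
#'
#' @param ring Numeric matrix with two columns (x, y).
#' @return Normalized open ring (matrix), or an error if fewer than 3
#'   distinct vertices remain.
#' @keywords internal
normalize_ring <- function(ring) {
  ring <- as.matrix(ring)
  stopifnot(ncol(ring) == 2, is.numeric(ring))
  n <- nrow(ring)
  if (n > 1 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  keep <- c(TRUE, rowSums(abs(diff(ring))) > 0)
  ring <- ring[keep, , drop = FALSE]
  if (nrow(ring) < 3) stop("polygon ring has fewer than 3 distinct vertices")
  ring
}

#' Shoelace area of a ring
#' @param ring Open ring matrix (x, y).
#' @return Non-negative area.
#' @keywords internal
ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

#' Is a ring simple (non-self-intersecting)?
#' @param ring Open ring matrix.
#' @keywords internal
is_simple_ring <- function(ring) {
  n <- nrow(ring)
  p1 <- ring
  p2 <- ring[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      adjacent <- j == i + 1 || (i == 1 && j == n)
      if (adjacent) next
      if (segments_cross(p1[i, ], p2[i, ], p1[j, ], p2[j, ])) return(FALSE)
    }
  }
  TRUE
}

# Proper or improper crossing of two closed segments (shared endpoints of
# adjacent edges are excluded by the caller).
segments_cross <- function(a1, a2, b1, b2) {
  d1 <- cross2(b2 - b1, a1 - b1)
  d2 <- cross2(b2 - b1, a2 - b1)
  d3 <- cross2(a2 - a1, b1 - a1)
  d4 <- cross2(a2 - a1, b2 - a1)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(p, q, r) { # r collinear with pq; is r within the box?
    min(p[1], q[1]) <= r[1] && r[1] <= max(p[1], q[1]) &&
      min(p[2], q[2]) <= r[2] && r[2] <= max(p[2], q[2])
  }
  (d1 == 0 && on_seg(b1, b2, a1)) || (d2 == 0 && on_seg(b1, b2, a2)) ||
    (d3 == 0 && on_seg(a1, a2, b1)) || (d4 == 0 && on_seg(a1, a2, b2))
}

cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]

# x-coordinates where the horizontal line y = ym crosses the boundary of
# a ring, using the half-open [ymin, ymax) edge convention.
ring_crossings <- function(ring, ym) {
  n <- nrow(ring)
  x1 <- ring[, 1]; y1 <- ring[, 2]
  x2 <- ring[c(2:n, 1), 1]; y2 <- ring[c(2:n, 1), 2]
  hit <- (y1 <= ym) != (y2 <= ym)
  if (!any(hit)) return(numeric(0))
  sort(x1[hit] + (ym - y1[hit]) * (x2[hit] - x1[hit]) / (y2[hit] - y1[hit]))
}

# Total length of the union of closed intervals given as a 2-column
# matrix (start, end).
interval_union_length <- function(iv) {
  if (nrow(iv) == 0) return(0)
  iv <- iv[iv[, 2] > iv[, 1], , drop = FALSE]
  if (nrow(iv) == 0) return(0)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  total <- 0
  cur_s <- iv[1, 1]; cur_e <- iv[1, 2]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] > cur_e) {
      total <- total + (cur_e - cur_s)
      cur_s <- iv[i, 1]; cur_e <- iv[i, 2]
    } else {
      cur_e <- max(cur_e, iv[i, 2])
    }
  }
  total + (cur_e - cur_s)
}

#' Exact area of (rectangle intersect union of polygons)
#'
#' @param rings List of open ring matrices (same class regions; overlap
#'   allowed).
#' @param rect Numeric `c(x0, y0, x1, y1)`, half-open axis-aligned
#'   rectangle.
#' @return Area of the union of the rings clipped to the rectangle.
#' @keywords internal
union_area_in_rect <- function(rings, rect) {
  x0 <- rect[1]; y0 <- rect[2]; x1 <- rect[3]; y1 <- rect[4]
  rings <- Filter(function(r) ring_area(r) > 0, rings)
  if (length(rings) == 0) return(0)

  # event ys: vertices, pairwise edge intersections, and crossings of the
  # rectangle's vertical boundaries (x-clipping kinks the interval length)
  ys <- unlist(lapply(rings, function(r) r[, 2]))
  edges <- do.call(rbind, lapply(rings, function(r) {
    n <- nrow(r)
    cbind(r, r[c(2:n, 1), , drop = FALSE])
  }))
  for (xb in c(x0, x1)) {
    spans <- (edges[, 1] <= xb) != (edges[, 3] <= xb)
    if (any(spans)) {
      e <- edges[spans, , drop = FALSE]
      ys <- c(ys, e[, 2] + (xb - e[, 1]) * (e[, 4] - e[, 2]) / (e[, 3] - e[, 1]))
    }
  }
  ne <- nrow(edges)
  if (ne > 1) {
    for (i in seq_len(ne - 1)) {
      a1 <- edges[i, 1:2]; a2 <- edges[i, 3:4]
      for (j in (i + 1):ne) {
        b1 <- edges[j, 1:2]; b2 <- edges[j, 3:4]
        d <- cross2(a2 - a1, b2 - b1)
        if (d == 0) next
        t <- cross2(b1 - a1, b2 - b1) / d
        u <- cross2(b1 - a1, a2 - a1) / d
        if (t >= 0 && t <= 1 && u >= 0 && u <= 1) {
          ys <- c(ys, a1[2] + t * (a2[2] - a1[2]))
        }
      }
    }
  }
  ys <- sort(unique(pmin(pmax(ys, y0), y1)))
  ys <- unique(c(y0, ys, y1))
  if (length(ys) < 2) return(0)

  area <- 0
  for (k in seq_len(length(ys) - 1)) {
    h <- ys[k + 1] - ys[k]
    if (h <= 0) next
    ym <- (ys[k] + ys[k + 1]) / 2
    iv <- do.call(rbind, lapply(rings, function(r) {
      xs <- ring_crossings(r, ym)
      if (length(xs) < 2) return(matrix(numeric(0), 0, 2))
      matrix(xs, ncol = 2, byrow = TRUE)
    }))
    if (is.null(iv) || nrow(iv) == 0) next
    iv[, 1] <- pmax(iv[, 1], x0)
    iv[, 2] <- pmin(iv[, 2], x1)
    area <- area + h * interval_union_length(iv)
  }
  area
}
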