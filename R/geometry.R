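# Planar polygon primitives for region masking and conservative regridding.
# Grids here are ~0.01 degree cells, so planar treatment of lon/lat is
# adequate; areas only ever appear as ratios over the same latitude band.

#' Point-in-polygon test (ray casting)
#'
#' Even-odd rule; points exactly on an edge follow the half-open
#' convention of the crossing test (deterministic, not symmetric).
#'
#' @param px,py Point coordinate vectors.
#' @param poly Two-column matrix of polygon vertices (closed or open ring).
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  poly <- close_ring(poly)
  n <- nrow(poly) - 1L
  inside <- rep(FALSE, length(px))
  xs <- poly[, 1]; ys <- poly[, 2]
  for (i in seq_len(n)) {
    x1 <- xs[i]; y1 <- ys[i]; x2 <- xs[i + 1L]; y2 <- ys[i + 1L]
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside
}

close_ring <- function(poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3L) stop("polygon needs at least 3 vertices")
  if (any(poly[1, ] != poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  poly
}

#' Signed polygon area (shoelace)
#' @param poly Two-column vertex matrix.
#' @return Signed area; positive for counter-clockwise rings.
#' @export
polygon_area <- function(poly) {
  poly <- close_ring(poly)
  x <- poly[, 1]; y <- poly[, 2]; n <- nrow(poly)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

#' Clip a polygon to an axis-aligned rectangle (Sutherland-Hodgman)
#'
#' @param poly Two-column vertex matrix.
#' @param xlo,xhi,ylo,yhi Rectangle bounds.
#' @return Clipped vertex matrix, possibly with 0 rows.
#' @export
clip_polygon_rect <- function(poly, xlo, xhi, ylo, yhi) {
  poly <- close_ring(poly)
  pts <- poly[-nrow(poly), , drop = FALSE]
  clip_edge <- function(pts, keep, intersect) {
    if (nrow(pts) == 0L) return(pts)
    out <- matrix(numeric(0), ncol = 2)
    n <- nrow(pts)
    for (i in seq_len(n)) {
      cur <- pts[i, ]; prv <- pts[if (i == 1L) n else i - 1L, ]
      cin <- keep(cur); pin <- keep(prv)
      if (cin) {
        if (!pin) out <- rbind(out, intersect(prv, cur))
        out <- rbind(out, cur)
      } else if (pin) {
        out <- rbind(out, intersect(prv, cur))
      }
    }
    out
  }
  ix <- function(p, q, at, axis) {
    t <- (at - p[axis]) / (q[axis] - p[axis])
    p + t * (q - p)
  }
  pts <- clip_edge(pts, function(p) p[1] >= xlo, function(p, q) ix(p, q, xlo, 1))
  pts <- clip_edge(pts, function(p) p[1] <= xhi, function(p, q) ix(p, q, xhi, 1))
  pts <- clip_edge(pts, function(p) p[2] >= ylo, function(p, q) ix(p, q, ylo, 2))
  pts <- clip_edge(pts, function(p) p[2] <= yhi, function(p, q) ix(p, q, yhi, 2))
  pts
}

# |area of poly inside rect|
rect_overlap_area <- function(poly, xlo, xhi, ylo, yhi) {
  clipped <- clip_polygon_rect(poly, xlo, xhi, ylo, yhi)
  if (nrow(clipped) < 3L) return(0)
  abs(polygon_area(clipped))
}
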