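# Planar geometry primitives used by the crosswalk and exposure modules.
#
# All coordinates are planar (a projected system with metric units); nothing
# here reprojects. A *ring* is a two-column numeric matrix of vertices (closed
# or open; it is closed internally). A *polygon* is a list of rings, the first
# being the shell and any others holes. A *geometry* (multipolygon) is a list
# of polygons.

.closeRing <- function(ring) {
  ring <- as.matrix(ring)
  stopifnot(ncol(ring) == 2, nrow(ring) >= 3)
  if (ring[1L, 1L] != ring[nrow(ring), 1L] || ring[1L, 2L] != ring[nrow(ring), 2L])
    ring <- rbind(ring, ring[1L, , drop = FALSE])
  ring
}

# Even-odd ray cast plus an explicit on-boundary test. Returns a list with
# logical vectors `inside` (strict, even-odd) and `boundary`.
.pipRing <- function(px, py, ring, eps = 1e-9) {
  ring <- .closeRing(ring)
  n <- nrow(ring) - 1L
  inside <- rep(FALSE, length(px))
  boundary <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    x1 <- ring[i, 1L]; y1 <- ring[i, 2L]
    x2 <- ring[i + 1L, 1L]; y2 <- ring[i + 1L, 2L]
    seglen <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    if (seglen == 0) next
    tol <- eps * max(1, seglen, abs(x1), abs(y1), abs(x2), abs(y2))
    # distance from point to the segment's supporting line, scaled by length
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    inBox <- px >= pmin(x1, x2) - tol & px <= pmax(x1, x2) + tol &
      py >= pmin(y1, y2) - tol & py <= pmax(y1, y2) + tol
    boundary <- boundary | (abs(cross) <= tol * seglen & inBox)
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  list(inside = inside, boundary = boundary)
}

#' Test whether points fall inside a polygon
#'
#' Boundary-inclusive point-in-polygon test on planar coordinates. A point on
#' the shell (or on a hole's boundary) counts as contained; a point strictly
#' inside a hole does not.
#'
#' @param px,py Numeric vectors of point coordinates.
#' @param polygon A list of rings (two-column vertex matrices); the first ring
#'   is the shell, any further rings are holes. A bare matrix is treated as a
#'   single shell.
#' @return Logical vector, one element per point.
#' @examples
#' sq <- list(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' pointInPolygon(c(0.5, 2, 1), c(0.5, 0.5, 1), sq)
#' @export
pointInPolygon <- function(px, py, polygon) {
  if (is.matrix(polygon)) polygon <- list(polygon)
  shell <- .pipRing(px, py, polygon[[1L]])
  res <- shell$inside | shell$boundary
  for (hole in polygon[-1L]) {
    h <- .pipRing(px, py, hole)
    res <- res & !(h$inside & !h$boundary)
  }
  res
}

# Containment in a multipolygon geometry (list of polygons).
.pipGeometry <- function(px, py, geometry) {
  res <- rep(FALSE, length(px))
  for (poly in geometry) res <- res | pointInPolygon(px, py, poly)
  res
}

# Signed shoelace area of one ring.
.ringAreaSigned <- function(ring) {
  ring <- .closeRing(ring)
  n <- nrow(ring)
  x <- ring[, 1L]; y <- ring[, 2L]
  sum(x[-n] * y[-1L] - x[-1L] * y[-n]) / 2
}

#' Area of a polygon
#'
#' Shoelace area of the shell minus the area of any holes.
#'
#' @inheritParams pointInPolygon
#' @return Non-negative numeric scalar.
#' @export
polygonArea <- function(polygon) {
  if (is.matrix(polygon)) polygon <- list(polygon)
  a <- abs(.ringAreaSigned(polygon[[1L]]))
  for (hole in polygon[-1L]) a <- a - abs(.ringAreaSigned(hole))
  a
}

# Sutherland-Hodgman clip of one ring against an axis-aligned rectangle.
# Returns a (possibly empty) vertex matrix.
.clipRingToRect <- function(ring, xmin, ymin, xmax, ymax) {
  ring <- .closeRing(ring)
  pts <- ring[-nrow(ring), , drop = FALSE]
  clipEdge <- function(pts, keep, intersect) {
    n <- nrow(pts)
    if (n == 0L) return(pts)
    out <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(n)) {
      cur <- pts[i, ]
      prev <- pts[if (i == 1L) n else i - 1L, ]
      curIn <- keep(cur); prevIn <- keep(prev)
      if (curIn) {
        if (!prevIn) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (prevIn) {
        out <- rbind(out, intersect(prev, cur))
      }
    }
    out
  }
  ix <- function(p, q, t) p + t * (q - p)
  pts <- clipEdge(pts, function(p) p[1L] >= xmin,
                  function(p, q) ix(p, q, (xmin - p[1L]) / (q[1L] - p[1L])))
  pts <- clipEdge(pts, function(p) p[1L] <= xmax,
                  function(p, q) ix(p, q, (xmax - p[1L]) / (q[1L] - p[1L])))
  pts <- clipEdge(pts, function(p) p[2L] >= ymin,
                  function(p, q) ix(p, q, (ymin - p[2L]) / (q[2L] - p[2L])))
  pts <- clipEdge(pts, function(p) p[2L] <= ymax,
                  function(p, q) ix(p, q, (ymax - p[2L]) / (q[2L] - p[2L])))
  pts
}

#' Area of the intersection of a polygon with an axis-aligned rectangle
#'
#' Used for areal-weighted aggregation of gridded values over block-group
#' polygons, with grid cells modelled as square footprints.
#'
#' @inheritParams pointInPolygon
#' @param xmin,ymin,xmax,ymax Rectangle bounds.
#' @return Non-negative numeric scalar.
#' @export
polygonRectIntersectionArea <- function(polygon, xmin, ymin, xmax, ymax) {
  if (is.matrix(polygon)) polygon <- list(polygon)
  clipped <- .clipRingToRect(polygon[[1L]], xmin, ymin, xmax, ymax)
  if (nrow(clipped) < 3L) return(0)
  a <- abs(.ringAreaSigned(clipped))
  for (hole in polygon[-1L]) {
    hc <- .clipRingToRect(hole, xmin, ymin, xmax, ymax)
    if (nrow(hc) >= 3L) a <- a - abs(.ringAreaSigned(hc))
  }
  max(a, 0)
}

# Index of the nearest (qx, qy) point for each (px, py), Euclidean distance.
.nearestIndex <- function(px, py, qx, qy) {
  vapply(seq_along(px), function(i) {
    which.min((qx - px[i])^2 + (qy - py[i])^2)
  }, integer(1L))
}

# Axis-aligned rectangle ring helper (counter-clockwise).
.rectRing <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}
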