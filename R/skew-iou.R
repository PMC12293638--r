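# Skew IOU between rotated rectangles via intersection-point collection,
# convex sorting and fan triangulation.
#
# The intersection of two convex polygons is convex; its vertices are exactly
# (a) the pairwise edge-edge intersection points and (b) the vertices of one
# polygon contained (inclusively) in the other. Collecting those into a set,
# sorting them counterclockwise about their centroid and fan-triangulating
# gives the intersection area; the IOU follows as I / (A + B - I).

# point-merge tolerance when assembling the intersection point set
.DEDUP_TOL <- 1e-9

#' Intersection point set of two convex polygons
#'
#' Collects every edge-edge intersection point of the two polygons together
#' with every vertex of one polygon lying inside or on the boundary of the
#' other. Near-duplicate points (within `tol`) are merged. For convex inputs
#' these points are precisely the vertices of the intersection polygon.
#'
#' @param a,b Vertex matrices (nx2) of convex polygons, vertices in order.
#' @param tol Merge tolerance for coincident points (input units).
#' @return An mx2 matrix of points; zero rows when the polygons are disjoint.
#' @export
intersection_points <- function(a, b, tol = .DEDUP_TOL) {
  stopifnot(is.matrix(a), ncol(a) == 2L, is.matrix(b), ncol(b) == 2L)
  pts <- rbind(
    edge_intersections(a, b),
    a[points_in_convex(a, b), , drop = FALSE],
    b[points_in_convex(b, a), , drop = FALSE]
  )
  dedup_points(pts, tol)
}

# all pairwise proper/improper segment intersection points between the edge
# sets of polygons a and b
edge_intersections <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  out <- vector("list", na * nb)
  k <- 0L
  for (i in seq_len(na)) {
    p1 <- a[i, ]; p2 <- a[(i %% na) + 1L, ]
    for (j in seq_len(nb)) {
      q1 <- b[j, ]; q2 <- b[(j %% nb) + 1L, ]
      pt <- segment_intersection(p1, p2, q1, q2)
      if (!is.null(pt)) {
        k <- k + 1L
        out[[k]] <- pt
      }
    }
  }
  if (k == 0L) return(matrix(numeric(0), 0L, 2L))
  do.call(rbind, out[seq_len(k)])
}

# intersection point of segments p1-p2 and q1-q2, or NULL; collinear overlap
# contributes the overlapping endpoints (their hull has zero extra area)
segment_intersection <- function(p1, p2, q1, q2, eps = 1e-12) {
  r <- p2 - p1
  s <- q2 - q1
  denom <- r[1] * s[2] - r[2] * s[1]
  qp <- q1 - p1
  if (abs(denom) < eps * max(1, sum(abs(r)) * sum(abs(s)))) {
    return(NULL) # parallel or collinear; endpoints handled by containment
  }
  t <- (qp[1] * s[2] - qp[2] * s[1]) / denom
  u <- (qp[1] * r[2] - qp[2] * r[1]) / denom
  if (t < -eps || t > 1 + eps || u < -eps || u > 1 + eps) return(NULL)
  p1 + t * r
}

# logical vector: which rows of pts lie inside or on convex polygon poly
points_in_convex <- function(pts, poly, eps = 1e-9) {
  n <- nrow(poly)
  # orientation sign of the polygon
  area2 <- sum(poly[, 1] * poly[c(2:n, 1), 2] - poly[c(2:n, 1), 1] * poly[, 2])
  sgn <- if (area2 >= 0) 1 else -1
  inside <- rep(TRUE, nrow(pts))
  scale <- max(abs(poly), 1)
  for (i in seq_len(n)) {
    p1 <- poly[i, ]; p2 <- poly[(i %% n) + 1L, ]
    cr <- (p2[1] - p1[1]) * (pts[, 2] - p1[2]) - (p2[2] - p1[2]) * (pts[, 1] - p1[1])
    inside <- inside & (sgn * cr >= -eps * scale)
  }
  inside
}

dedup_points <- function(pts, tol = .DEDUP_TOL) {
  if (nrow(pts) <= 1L) return(pts)
  keep <- rep(TRUE, nrow(pts))
  for (i in 2:nrow(pts)) {
    if (!keep[i]) next
    prev <- pts[seq_len(i - 1L), , drop = FALSE][keep[seq_len(i - 1L)], , drop = FALSE]
    if (nrow(prev) &&
        any(abs(prev[, 1] - pts[i, 1]) <= tol & abs(prev[, 2] - pts[i, 2]) <= tol)) {
      keep[i] <- FALSE
    }
  }
  pts[keep, , drop = FALSE]
}

#' Sort points into a counterclockwise convex polygon
#'
#' Orders a point set (assumed to lie on a common convex hull, as the
#' intersection vertices of two convex polygons do) counterclockwise by angle
#' about the centroid, merging near-duplicates. Fewer than 3 distinct points
#' yield a degenerate polygon of zero area.
#'
#' @param points An nx2 matrix.
#' @param tol Duplicate-merge tolerance.
#' @return An mx2 matrix of counterclockwise-ordered vertices.
#' @export
convex_sort <- function(points, tol = .DEDUP_TOL) {
  stopifnot(is.matrix(points), ncol(points) == 2L)
  pts <- dedup_points(points, tol)
  if (nrow(pts) < 3L) return(pts)
  ctr <- colMeans(pts)
  ang <- atan2(pts[, 2] - ctr[2], pts[, 1] - ctr[1])
  pts[order(ang), , drop = FALSE]
}

#' Polygon area by fan triangulation
#'
#' Splits a convex polygon into triangles fanning out from its first vertex
#' and sums the (absolute) triangle areas. For counterclockwise convex input
#' this equals the shoelace area; any fan anchor gives the same value.
#'
#' @param poly An nx2 matrix of ordered convex-polygon vertices.
#' @return Nonnegative area (squared input units); 0 for fewer than 3 vertices.
#' @export
polygon_area <- function(poly) {
  stopifnot(is.matrix(poly), ncol(poly) == 2L)
  n <- nrow(poly)
  if (n < 3L) return(0)
  a <- 0
  for (i in 2:(n - 1L)) {
    v1 <- poly[i, ] - poly[1, ]
    v2 <- poly[i + 1L, ] - poly[1, ]
    a <- a + abs(v1[1] * v2[2] - v1[2] * v2[1]) / 2
  }
  a
}

#' Intersection polygon of two rotated boxes
#'
#' @param p,q [rotated_box()] objects.
#' @return An mx2 matrix of counterclockwise intersection-polygon vertices
#'   (zero rows / degenerate when the boxes do not overlap).
#' @export
box_intersection_polygon <- function(p, q) {
  convex_sort(intersection_points(box_corners(p), box_corners(q)))
}

#' Skew IOU of two rotated boxes
#'
#' Exact intersection-over-union between rotated rectangles: the intersection
#' polygon is assembled from edge-edge intersection points plus contained
#' vertices, sorted convex, fan-triangulated for its area `I`, and the ratio
#' `I / (area(p) + area(q) - I)` is returned.
#'
#' @param p,q [rotated_box()] objects.
#' @return IOU in `[0, 1]`; symmetric in its arguments.
#' @examples
#' a <- rotated_box(0, 0, 1, 1, 0)
#' skew_iou(a, rotated_box(0.5, 0, 1, 1, 0)) # 1/3
#' skew_iou(a, rotated_box(0, 0, 1, 1, pi / 4))
#' @export
skew_iou <- function(p, q) {
  stopifnot(is_rotated_box(p), is_rotated_box(q))
  inter <- polygon_area(box_intersection_polygon(p, q))
  ap <- p$w * p$h
  aq <- q$w * q$h
  denom <- ap + aq - inter
  if (denom <= 0) return(0)
  max(0, min(1, inter / denom))
}
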