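#' Rotated bounding box
#'
#' Construct a rotated (oriented) bounding box, the basic currency of the
#' package. A box is parameterized by its center `(cx, cy)`, its side lengths
#' `w` (along the box's own x-axis) and `h` (along its own y-axis), and a
#' rotation angle `theta` in radians measured from the image x-axis.
#' Coordinates follow the image convention: x rightward, y downward.
#'
#' `theta` is stored normalized to `[-pi/2, pi/2)`; a rotated rectangle is
#' invariant under `theta -> theta + pi`, so normalization never needs to swap
#' `w` and `h`. The representation `(w, h, theta)` and `(h, w, theta + pi/2)`
#' describe the same rectangle; [canonical_box()] resolves that symmetry.
#'
#' @param cx,cy Box center.
#' @param w,h Side lengths, both strictly positive.
#' @param theta Rotation angle in radians; any finite value is accepted and
#'   normalized.
#' @return An object of class `rotated_box`.
#' @examples
#' b <- rotated_box(320, 240, 200, 80, 0.1)
#' box_corners(b)
#' @export
rotated_box <- function(cx, cy, w, h, theta = 0) {
  stopifnot(
    is.numeric(cx), is.numeric(cy), is.numeric(w), is.numeric(h),
    is.numeric(theta),
    length(cx) == 1L, length(cy) == 1L, length(w) == 1L, length(h) == 1L,
    length(theta) == 1L,
    is.finite(cx), is.finite(cy), is.finite(theta)
  )
  if (!is.finite(w) || !is.finite(h) || w <= 0 || h <= 0) {
    stop("box side lengths 'w' and 'h' must be finite and > 0")
  }
  structure(
    list(cx = as.numeric(cx), cy = as.numeric(cy),
         w = as.numeric(w), h = as.numeric(h),
         theta = normalize_angle(as.numeric(theta))),
    class = "rotated_box"
  )
}

#' Normalize an angle to the half-open interval [-pi/2, pi/2)
#'
#' Rotated rectangles have period pi in their angle, so any angle dialect
#' (e.g. roLabelImg's `[0, 2*pi)` clockwise screen-space angle) reduces to this
#' range without touching `w` and `h`.
#'
#' @param theta Angle(s) in radians.
#' @return Angle(s) in `[-pi/2, pi/2)`.
#' @export
normalize_angle <- function(theta) {
  ((theta + pi / 2) %% pi) - pi / 2
}

#' @export
print.rotated_box <- function(x, ...) {
  cat(sprintf(
    "<rotated_box> center (%.4g, %.4g)  w %.4g  h %.4g  theta %.4g rad (%.2f deg)\n",
    x$cx, x$cy, x$w, x$h, x$theta, x$theta * 180 / pi
  ))
  invisible(x)
}

#' @export
format.rotated_box <- function(x, ...) {
  sprintf("rotated_box(%.6g, %.6g, %.6g, %.6g, %.6g)", x$cx, x$cy, x$w, x$h, x$theta)
}

is_rotated_box <- function(x) inherits(x, "rotated_box")

#' Corner coordinates of a rotated box
#'
#' Expands a box to its 4 corners in counterclockwise order (in the stored
#' coordinate convention); the centroid of the corners equals the box center.
#'
#' @param box A [rotated_box()].
#' @return A 4x2 numeric matrix of `(x, y)` corners.
#' @export
box_corners <- function(box) {
  stopifnot(is_rotated_box(box))
  ct <- cos(box$theta); st <- sin(box$theta)
  # local corners in CCW order for a right-handed (x, y) pair
  lx <- c(-1, 1, 1, -1) * box$w / 2
  ly <- c(-1, -1, 1, 1) * box$h / 2
  cbind(
    x = box$cx + lx * ct - ly * st,
    y = box$cy + lx * st + ly * ct
  )
}

#' Re-fit a rotated box to four rectangle corners
#'
#' Inverse of [box_corners()]: given the 4 corners of a (possibly rotated)
#' rectangle in any cyclic order, recovers `(cx, cy, w, h, theta)`. The result
#' equals the original box up to the `(w, h, theta)` / `(h, w, theta + pi/2)`
#' symmetry. For non-rectangular quadrilaterals use [min_area_box()].
#'
#' @param corners A 4x2 numeric matrix.
#' @return A [rotated_box()].
#' @export
corners_to_box <- function(corners) {
  stopifnot(is.matrix(corners), nrow(corners) == 4L, ncol(corners) == 2L)
  e1 <- corners[2, ] - corners[1, ]
  e2 <- corners[4, ] - corners[1, ]
  w <- sqrt(sum(e1^2)); h <- sqrt(sum(e2^2))
  theta <- atan2(e1[2], e1[1])
  ctr <- colMeans(corners)
  b <- rotated_box(ctr[1], ctr[2], w, h, theta)
  # keep (w, h) attached to the edge that defined theta: if normalization moved
  # theta by an odd multiple of pi/2 nothing changes (period is pi), so done.
  b
}

#' Canonical representation of a rotated box
#'
#' Resolves the `(w, h, theta)` / `(h, w, theta + pi/2)` symmetry by returning
#' the representation whose first side is the long one (`w >= h`), with the
#' angle renormalized. Useful for comparing boxes produced by different paths.
#'
#' @param box A [rotated_box()].
#' @return A [rotated_box()] with `w >= h`.
#' @export
canonical_box <- function(box) {
  stopifnot(is_rotated_box(box))
  if (box$w >= box$h) return(box)
  rotated_box(box$cx, box$cy, box$h, box$w, box$theta + pi / 2)
}

#' Minimum-area enclosing rotated box
#'
#' Rotating-calipers fit over the convex hull of a point set: for each hull
#' edge direction, the points are projected onto the edge frame and the
#' tightest axis-aligned rectangle in that frame is measured; the direction
#' with minimal area wins. Used to re-fit boxes after non-rigid (e.g.
#' anisotropic stretch) transforms that do not preserve rectangles.
#'
#' @param points An nx2 numeric matrix, n >= 3 and not all collinear.
#' @return A [rotated_box()].
#' @export
min_area_box <- function(points) {
  stopifnot(is.matrix(points), ncol(points) == 2L, nrow(points) >= 3L)
  hull <- points[grDevices::chull(points), , drop = FALSE]
  n <- nrow(hull)
  if (n < 3L) stop("points are collinear; no enclosing box of positive area")
  best <- NULL
  for (i in seq_len(n)) {
    e <- hull[(i %% n) + 1L, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-300) next
    u <- e / len
    v <- c(-u[2], u[1])
    pu <- hull %*% u
    pv <- hull %*% v
    w <- max(pu) - min(pu)
    h <- max(pv) - min(pv)
    if (is.null(best) || w * h < best$area) {
      cu <- (max(pu) + min(pu)) / 2
      cv <- (max(pv) + min(pv)) / 2
      best <- list(
        area = w * h,
        cx = cu * u[1] + cv * v[1],
        cy = cu * u[2] + cv * v[2],
        w = w, h = h, theta = atan2(u[2], u[1])
      )
    }
  }
  rotated_box(best$cx, best$cy, max(best$w, 1e-12), max(best$h, 1e-12), best$theta)
}

#' Apply a rigid motion (rotation + translation) to a rotated box
#'
#' @param box A [rotated_box()].
#' @param angle Rotation in radians about `center`.
#' @param shift Length-2 translation applied after the rotation.
#' @param center Length-2 rotation center (default the origin).
#' @return The transformed [rotated_box()].
#' @export
transform_box <- function(box, angle = 0, shift = c(0, 0), center = c(0, 0)) {
  stopifnot(is_rotated_box(box))
  ca <- cos(angle); sa <- sin(angle)
  dx <- box$cx - center[1]; dy <- box$cy - center[2]
  rotated_box(
    center[1] + dx * ca - dy * sa + shift[1],
    center[2] + dx * sa + dy * ca + shift[2],
    box$w, box$h, box$theta + angle
  )
}
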