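#' Grid-sampling reference IOU for rotated boxes
#'
#' Estimates the IOU of two rotated boxes by counting lattice points: an
#' `n` x `n` grid of cell centers covers the joint axis-aligned bounding box
#' of the pair, and membership in each rectangle is tested in the rectangle's
#' own frame. Entirely independent of the polygon-triangulation route in
#' [skew_iou()], which makes it a useful numerical cross-check; the
#' discretization error shrinks like `1/n`.
#'
#' @param p,q [rotated_box()] objects.
#' @param n Grid resolution per axis (default 2000).
#' @return Approximate IOU in `[0, 1]`.
#' @export
raster_iou <- function(p, q, n = 2000L) {
  stopifnot(is_rotated_box(p), is_rotated_box(q))
  raster_iou_cpp(
    c(p$cx, p$cy, p$w, p$h, p$theta),
    c(q$cx, q$cy, q$w, q$h, q$theta),
    as.integer(n)
  )
}
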