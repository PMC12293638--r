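# Head-tilt-correcting eye-region crop and the upload quality-assurance gate.

#' Ocular alignment angle of an eye-region box
#'
#' The signed angle between the box's long axis (the inter-eye axis for an
#' eye-region box) and the image horizontal, in `[-pi/2, pi/2)` radians. When
#' the stored representation has `h > w` the axes are swapped first so the
#' long axis is always the one measured; for an exactly square box the stored
#' angle is returned and the result carries attribute `axis_ambiguous = TRUE`.
#'
#' @param box A [rotated_box()].
#' @return Angle in radians; attribute `axis_ambiguous` flags square boxes.
#' @export
alignment_angle <- function(box) {
  stopifnot(is_rotated_box(box))
  cb <- canonical_box(box)
  ang <- cb$theta
  if (box$w == box$h) attr(ang, "axis_ambiguous") <- TRUE
  ang
}

#' Eye-region area fraction of the image frame
#'
#' `w * h / (W * H)`: the proportion of the photo covered by the (rotated)
#' box; rotation preserves area, so the angle plays no role. Boxes are clipped
#' conceptually to the frame, but since detections live inside the frame the
#' raw product is used.
#'
#' @param box A [rotated_box()] in pixel coordinates.
#' @param image_size `c(width, height)` in pixels.
#' @return Fraction in `[0, 1]` (capped at 1).
#' @export
area_fraction <- function(box, image_size) {
  stopifnot(is_rotated_box(box), length(image_size) == 2L)
  W <- image_size[[1]]; H <- image_size[[2]]
  if (W <= 0 || H <= 0) stop("image area must be positive")
  min(1, (box$w * box$h) / (W * H))
}

#' Deskewing crop of the eye region
#'
#' Rotates the image content by minus the box's [alignment_angle()] about the
#' box center and crops the axis-aligned window of size
#' `(1 + 2 * margin_factor) * (w, h)` (long axis first), so the inter-eye
#' axis is horizontal in the output. Resampling is bilinear; samples falling
#' outside the source are filled with grey and flagged.
#'
#' @param image Grey image matrix.
#' @param box A [rotated_box()] locating the eye region.
#' @param margin_factor Fraction of the box size added per side (default 0;
#'   0.1 grows each axis by 20% in total).
#' @param fill Grey level for out-of-source samples.
#' @return A list of class `crop_result`: `image` (the deskewed crop),
#'   `applied_rotation` (radians the content was rotated by, = -alignment
#'   angle), `source_box`, `margin_factor`, `padded` (TRUE when the window
#'   left the source frame).
#' @export
deskew_crop <- function(image, box, margin_factor = 0, fill = .FILL_GREY) {
  image <- as_grey_matrix(image)
  stopifnot(is_rotated_box(box), margin_factor >= 0)
  cb <- canonical_box(box) # long axis first
  alpha <- cb$theta
  out_w <- max(1L, as.integer(round(cb$w * (1 + 2 * margin_factor))))
  out_h <- max(1L, as.integer(round(cb$h * (1 + 2 * margin_factor))))
  ca <- cos(alpha); sa <- sin(alpha)
  # output pixel at offset d from the output center samples the source at
  # box_center + R(alpha) d
  A <- matrix(c(ca, sa, -sa, ca), 2, 2)
  b <- c(cb$cx, cb$cy) - A %*% c(out_w / 2, out_h / 2)
  out <- affine_resample(image, A, as.numeric(b), out_w, out_h, fill)
  # did the sampling window leave the source frame?
  crn_out <- cbind(c(0, out_w, out_w, 0), c(0, 0, out_h, out_h))
  crn_src <- t(A %*% t(crn_out) + as.numeric(b))
  padded <- any(crn_src[, 1] < 0 | crn_src[, 1] > img_width(image) |
                  crn_src[, 2] < 0 | crn_src[, 2] > img_height(image))
  if (padded) log_event("deskew_crop: window exceeds source frame; padded with fill")
  structure(
    list(image = out, applied_rotation = -alpha, source_box = box,
         margin_factor = margin_factor, padded = padded),
    class = "crop_result"
  )
}

#' @export
print.crop_result <- function(x, ...) {
  cat(sprintf("<crop_result> %dx%d  rotation applied %.3f rad (%.2f deg)  margin %.2f%s\n",
              ncol(x$image), nrow(x$image), x$applied_rotation,
              x$applied_rotation * 180 / pi, x$margin_factor,
              if (x$padded) "  [padded]" else ""))
  invisible(x)
}

#' Upload quality-assurance gate
#'
#' The dual-layer check applied to an uploaded ocular-gaze photograph:
#' \itemize{
#'   \item resolution: the photo must have at least `min_megapixels`
#'     (default 5 MP); smaller images fail the pre-model check.
#'   \item shooting distance: the detected eye region must cover between
#'     `area_min` (2.5%) and `area_max` (25%) of the frame; below is flagged
#'     "too far", above "too close".
#'   \item reliability: the detection confidence must reach `min_confidence`
#'     (50%); below that - or when no detection is supplied at all - the
#'     image is flagged unreliable.
#' }
#' The printed thresholds are phrased as "less than" / "more than" / "falls
#' below", so values exactly on a boundary pass.
#'
#' @param image_size `c(width, height)` in pixels.
#' @param detection A [detection()] or `NULL` when the detector found
#'   nothing.
#' @param config A configuration list as from [default_config()]; the fields
#'   `qa_min_megapixels`, `qa_area_min`, `qa_area_max`, `qa_min_confidence`
#'   are used.
#' @return An object of class `qa_report` with fields `resolution_ok`,
#'   `megapixels`, `distance_status` (`"ok"`, `"too_far"`, `"too_close"`, or
#'   `"no_detection"`), `area_fraction`, `confidence_ok`, `confidence` and
#'   the overall `accepted` flag.
#' @examples
#' det <- detection(rotated_box(1500, 1000, 800, 750, 0.05), 0.9)
#' qa_gate(c(3000, 2000), det)
#' @export
qa_gate <- function(image_size, detection = NULL, config = default_config()) {
  stopifnot(length(image_size) == 2L, all(image_size > 0))
  mp <- image_size[[1]] * image_size[[2]] / 1e6
  resolution_ok <- mp >= config$qa_min_megapixels
  if (is.null(detection)) {
    rep <- list(resolution_ok = resolution_ok, megapixels = mp,
                distance_status = "no_detection", area_fraction = NA_real_,
                confidence_ok = FALSE, confidence = NA_real_,
                accepted = FALSE, reason = "no detection: image unreliable")
    return(structure(rep, class = "qa_report"))
  }
  stopifnot(inherits(detection, "detection"))
  af <- area_fraction(detection$box, image_size)
  distance_status <- if (af < config$qa_area_min) "too_far"
    else if (af > config$qa_area_max) "too_close" else "ok"
  confidence_ok <- detection$confidence >= config$qa_min_confidence
  accepted <- resolution_ok && distance_status == "ok" && confidence_ok
  reason <- if (accepted) "accepted" else paste(
    c(if (!resolution_ok) sprintf("resolution %.2f MP below minimum", mp),
      if (distance_status != "ok") sprintf("distance %s", distance_status),
      if (!confidence_ok) "detection confidence below 50%: unreliable"),
    collapse = "; ")
  structure(
    list(resolution_ok = resolution_ok, megapixels = mp,
         distance_status = distance_status, area_fraction = af,
         confidence_ok = confidence_ok, confidence = detection$confidence,
         accepted = accepted, reason = reason),
    class = "qa_report"
  )
}

#' @export
print.qa_report <- function(x, ...) {
  cat("<qa_report>\n")
  cat(sprintf("  resolution: %.2f MP  [%s]\n", x$megapixels,
              if (x$resolution_ok) "ok" else "too low"))
  cat(sprintf("  eye-region area: %s  [%s]\n",
              if (is.na(x$area_fraction)) "-" else sprintf("%.1f%%", 100 * x$area_fraction),
              x$distance_status))
  cat(sprintf("  confidence: %s  [%s]\n",
              if (is.na(x$confidence)) "-" else sprintf("%.2f", x$confidence),
              if (x$confidence_ok) "ok" else "unreliable"))
  cat(sprintf("  => %s\n", if (x$accepted) "ACCEPTED" else paste("REJECTED:", x$reason)))
  invisible(x)
}

#' Serialize a QA report as key-value text
#'
#' @param x A `qa_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_qa_report <- function(x, path) {
  stopifnot(inherits(x, "qa_report"))
  writeLines(c(
    sprintf("resolution_ok: %s", tolower(x$resolution_ok)),
    sprintf("megapixels: %.6f", x$megapixels),
    sprintf("distance_status: %s", x$distance_status),
    sprintf("area_fraction: %s",
            if (is.na(x$area_fraction)) "NA" else sprintf("%.6f", x$area_fraction)),
    sprintf("confidence_ok: %s", tolower(x$confidence_ok)),
    sprintf("confidence: %s",
            if (is.na(x$confidence)) "NA" else sprintf("%.6f", x$confidence)),
    sprintf("accepted: %s", tolower(x$accepted))
  ), path)
  invisible(path)
}
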