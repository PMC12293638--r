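# Annotation format readers/writers: roLabelImg XML (robndbox dialect) and
# YOLO-OBB normalized text. All internal angles use the package convention
# (radians, normalized to [-pi/2, pi/2)); dialect conversion happens at the
# boundary.

log_event <- function(fmt, ...) {
  lvl <- getOption("periocrop.log_level", "warn")
  if (identical(lvl, "quiet")) return(invisible(NULL))
  message(sprintf(paste0("[periocrop] ", fmt), ...))
  invisible(NULL)
}

#' Annotated image record
#'
#' Bundles an image reference, its pixel dimensions and its ground-truth
#' rotated boxes (pixel coordinates). Boxes whose centers fall outside the
#' frame are rejected; boxes extending past the frame are kept but logged.
#'
#' @param image_path Path (or identifier) of the image.
#' @param image_size `c(width, height)` in pixels.
#' @param boxes List of [rotated_box()]es.
#' @param source_format Dialect tag, e.g. `"rolabelimg"` or `"yolo_obb"`.
#' @return An object of class `annotated_image`.
#' @export
annotated_image <- function(image_path, image_size, boxes = list(),
                            source_format = "memory") {
  stopifnot(length(image_size) == 2L, all(image_size > 0))
  boxes <- as_box_list(boxes)
  W <- image_size[[1]]; H <- image_size[[2]]
  for (b in boxes) {
    if (b$cx < 0 || b$cx > W || b$cy < 0 || b$cy > H) {
      stop(sprintf("box center (%.1f, %.1f) outside the %gx%g frame",
                   b$cx, b$cy, W, H))
    }
    crn <- box_corners(b)
    if (any(crn[, 1] < 0 | crn[, 1] > W | crn[, 2] < 0 | crn[, 2] > H)) {
      log_event("box at (%.1f, %.1f) in '%s' extends past the frame",
                b$cx, b$cy, image_path)
    }
  }
  structure(
    list(image_path = as.character(image_path),
         image_size = c(width = as.numeric(W), height = as.numeric(H)),
         boxes = boxes, source_format = source_format),
    class = "annotated_image"
  )
}

#' @export
print.annotated_image <- function(x, ...) {
  cat(sprintf("<annotated_image> '%s' %gx%g, %d box(es) [%s]\n",
              x$image_path, x$image_size[1], x$image_size[2],
              length(x$boxes), x$source_format))
  invisible(x)
}

xml_num <- function(node, name, path) {
  child <- xml2::xml_find_first(node, name)
  if (inherits(child, "xml_missing")) {
    stop(sprintf("malformed annotation '%s': missing element <%s>", path, name))
  }
  val <- suppressWarnings(as.numeric(xml2::xml_text(child)))
  if (is.na(val)) {
    stop(sprintf("malformed annotation '%s': non-numeric <%s> value '%s'",
                 path, name, xml2::xml_text(child)))
  }
  val
}

#' Read a roLabelImg XML annotation
#'
#' Parses `<robndbox>` records (`cx`, `cy`, `w`, `h`, `angle`). roLabelImg
#' stores angles in `[0, 2*pi)` measured clockwise from the x-axis in screen
#' coordinates, which coincides with this package's positive direction in the
#' y-down convention; angles are normalized into `[-pi/2, pi/2)` on read (a
#' rotated rectangle has angle period pi, so `w`/`h` are untouched). The
#' original angle values are preserved in the `raw_angles` attribute.
#'
#' @param xml_path Path to the XML file.
#' @return An [annotated_image()].
#' @export
read_rolabelimg <- function(xml_path) {
  doc <- tryCatch(xml2::read_xml(xml_path), error = function(e) {
    stop(sprintf("malformed annotation '%s': %s", xml_path, conditionMessage(e)))
  })
  size <- xml2::xml_find_first(doc, ".//size")
  if (inherits(size, "xml_missing")) {
    stop(sprintf("malformed annotation '%s': missing element <size>", xml_path))
  }
  W <- xml_num(size, "width", xml_path)
  H <- xml_num(size, "height", xml_path)
  img_path <- xml2::xml_text(xml2::xml_find_first(doc, ".//path"))
  if (is.na(img_path) || !nzchar(img_path)) {
    img_path <- xml2::xml_text(xml2::xml_find_first(doc, ".//filename"))
  }
  rb_nodes <- xml2::xml_find_all(doc, ".//object/robndbox")
  raw_angles <- numeric(0)
  boxes <- lapply(rb_nodes, function(nd) {
    ang <- xml_num(nd, "angle", xml_path)
    raw_angles[length(raw_angles) + 1L] <<- ang
    rotated_box(xml_num(nd, "cx", xml_path), xml_num(nd, "cy", xml_path),
                xml_num(nd, "w", xml_path), xml_num(nd, "h", xml_path), ang)
  })
  ann <- annotated_image(img_path, c(W, H), boxes, source_format = "rolabelimg")
  attr(ann, "raw_angles") <- raw_angles
  ann
}

#' Write a roLabelImg XML annotation
#'
#' @param annot An [annotated_image()].
#' @param path Output XML path.
#' @param object_name Label written for every box (single-class task).
#' @return `path`, invisibly.
#' @export
write_rolabelimg <- function(annot, path, object_name = "eye_region") {
  stopifnot(inherits(annot, "annotated_image"))
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", basename(annot$image_path))
  xml2::xml_add_child(doc, "path", annot$image_path)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", format(annot$image_size[["width"]]))
  xml2::xml_add_child(size, "height", format(annot$image_size[["height"]]))
  xml2::xml_add_child(size, "depth", "1")
  for (b in annot$boxes) {
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "type", "robndbox")
    xml2::xml_add_child(obj, "name", object_name)
    rb <- xml2::xml_add_child(obj, "robndbox")
    # write the stored dialect: angle in [0, 2*pi)
    xml2::xml_add_child(rb, "cx", sprintf("%.9f", b$cx))
    xml2::xml_add_child(rb, "cy", sprintf("%.9f", b$cy))
    xml2::xml_add_child(rb, "w", sprintf("%.9f", b$w))
    xml2::xml_add_child(rb, "h", sprintf("%.9f", b$h))
    xml2::xml_add_child(rb, "angle", sprintf("%.9f", b$theta %% (2 * pi)))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write YOLO-OBB annotation lines
#'
#' One line per box: `class_id cx cy w h theta`, with `cx`, `w` normalized by
#' the image width, `cy`, `h` by the height, and `theta` in radians; nine
#' decimals give a bit-exact round trip at 1e-9. The class id is fixed at 0
#' (single-class `eye_region` task).
#'
#' @param annot An [annotated_image()].
#' @param path Output text path.
#' @return `path`, invisibly.
#' @export
write_yolo_obb <- function(annot, path) {
  stopifnot(inherits(annot, "annotated_image"))
  W <- annot$image_size[["width"]]; H <- annot$image_size[["height"]]
  lines <- vapply(annot$boxes, function(b) {
    vals <- c(b$cx / W, b$cy / H, b$w / W, b$h / H)
    if (any(vals < 0 | vals > 1)) {
      stop(sprintf("box %s does not normalize into [0,1] for a %gx%g image",
                   format(b), W, H))
    }
    sprintf("0 %.9f %.9f %.9f %.9f %.9f", vals[1], vals[2], vals[3], vals[4],
            b$theta)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read YOLO-OBB annotation lines
#'
#' @param path Text file with `class cx cy w h theta` lines (normalized
#'   coordinates).
#' @param image_size `c(width, height)` used to denormalize.
#' @param image_path Identifier stored in the result.
#' @return An [annotated_image()].
#' @export
read_yolo_obb <- function(path, image_size, image_path = path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  W <- image_size[[1]]; H <- image_size[[2]]
  boxes <- lapply(seq_along(lines), function(k) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(lines[k]), "\\s+")[[1]]))
    if (length(f) < 6 || any(is.na(f[1:6]))) {
      stop(sprintf("malformed annotation '%s': line %d is not 'class cx cy w h theta'",
                   path, k))
    }
    rotated_box(f[2] * W, f[3] * H, f[4] * W, f[5] * H, f[6])
  })
  annotated_image(image_path, image_size, boxes, source_format = "yolo_obb")
}

#' Read detections from an extended YOLO-OBB file
#'
#' Detection files use the YOLO-OBB line layout with a seventh confidence
#' field: `class cx cy w h theta conf`.
#'
#' @inheritParams read_yolo_obb
#' @param image_id Identifier attached to the detections.
#' @return A list of [detection()]s.
#' @export
read_detections <- function(path, image_size, image_id = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  W <- image_size[[1]]; H <- image_size[[2]]
  lapply(seq_along(lines), function(k) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(lines[k]), "\\s+")[[1]]))
    if (length(f) < 7 || any(is.na(f[1:7]))) {
      stop(sprintf("malformed detections '%s': line %d is not 'class cx cy w h theta conf'",
                   path, k))
    }
    detection(rotated_box(f[2] * W, f[3] * H, f[4] * W, f[5] * H, f[6]),
              f[7], image_id)
  })
}

#' Write detections as extended YOLO-OBB lines
#'
#' @param dets List of [detection()]s.
#' @param image_size `c(width, height)` used to normalize.
#' @param path Output text path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(dets, image_size, path) {
  dets <- as_detection_list(dets)
  W <- image_size[[1]]; H <- image_size[[2]]
  lines <- vapply(dets, function(d) {
    b <- d$box
    sprintf("0 %.9f %.9f %.9f %.9f %.9f %.9f",
            b$cx / W, b$cy / H, b$w / W, b$h / H, b$theta, d$confidence)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
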