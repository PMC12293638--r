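# Letterbox resizing to the square network input and mosaic augmentation
# combining four annotated images, plus the standard photometric
# augmentations (anisotropic stretch, Gaussian blur, contrast).

#' Letterbox an image (and its boxes) to a square side
#'
#' Scales the content uniformly by `side / max(W, H)` (preserving aspect
#' ratio), centers it on a square canvas of the requested side and pads the
#' remainder with a fixed grey. Boxes are mapped by the same scale and offset;
#' their angle is unchanged under a uniform scale.
#'
#' @param image Grey image matrix (see [read_image()]).
#' @param boxes Optional list of [rotated_box()]es in source pixel
#'   coordinates.
#' @param side Target square side in pixels (default 640).
#' @param fill Pad grey level in `[0, 1]` (default 114/255).
#' @return A list of class `letterbox_result`: `image` (side x side), `scale`,
#'   `pad` (left, top, right, bottom), `boxes` (transformed).
#' @examples
#' img <- matrix(runif(72 * 128), 72, 128)
#' lb <- letterbox(img, side = 64)
#' lb$scale; lb$pad
#' @export
letterbox <- function(image, boxes = list(), side = 640L, fill = .FILL_GREY) {
  image <- as_grey_matrix(image)
  w <- img_width(image); h <- img_height(image)
  if (w == 0 || h == 0) stop("cannot letterbox a zero-size image")
  side <- as.integer(side)
  scale <- side / max(w, h)
  new_w <- as.integer(round(w * scale))
  new_h <- as.integer(round(h * scale))
  pad_l <- (side - new_w) %/% 2L
  pad_t <- (side - new_h) %/% 2L
  pad <- c(left = pad_l, top = pad_t,
           right = side - new_w - pad_l, bottom = side - new_h - pad_t)
  # out -> in: x_in = (x_out - pad_l) / scale
  out <- affine_resample(image,
                         A = diag(2) / scale,
                         b = c(-pad_l / scale, -pad_t / scale),
                         out_w = side, out_h = side, fill = fill)
  # content region sampled exactly; fill outside content, not just outside canvas
  if (pad_l > 0 || pad["right"] > 0) {
    cols <- c(seq_len(pad_l), if (pad["right"] > 0) (side - pad[["right"]] + 1L):side)
    out[, cols] <- fill
  }
  if (pad_t > 0 || pad["bottom"] > 0) {
    rows <- c(seq_len(pad_t), if (pad["bottom"] > 0) (side - pad[["bottom"]] + 1L):side)
    out[rows, ] <- fill
  }
  boxes_t <- lapply(as_box_list(boxes), function(b) {
    rotated_box(b$cx * scale + pad_l, b$cy * scale + pad_t,
                b$w * scale, b$h * scale, b$theta)
  })
  structure(list(image = out, scale = scale, pad = pad, boxes = boxes_t,
                 source_size = c(width = w, height = h)),
            class = "letterbox_result")
}

#' Map a letterboxed box back to original-image coordinates
#'
#' Inverse of the box transform applied by [letterbox()]; round-trips within
#' 0.5 px.
#'
#' @param result A `letterbox_result`.
#' @param box A [rotated_box()] in letterboxed coordinates.
#' @return The [rotated_box()] in source-image coordinates.
#' @export
letterbox_unmap_box <- function(result, box) {
  stopifnot(inherits(result, "letterbox_result"), is_rotated_box(box))
  s <- result$scale
  rotated_box((box$cx - result$pad[["left"]]) / s,
              (box$cy - result$pad[["top"]]) / s,
              box$w / s, box$h / s, box$theta)
}

# Clip a rotated box to an axis-aligned window [x0,x1] x [y0,y1], shrinking
# its extent along its own axes but preserving its angle. Returns NULL when
# the overlap is (near) empty.
clip_box_to_rect <- function(box, x0, x1, y0, y1) {
  rect <- cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
  poly <- convex_sort(intersection_points(box_corners(box), rect))
  if (nrow(poly) < 3L || polygon_area(poly) < 1e-9) return(NULL)
  u <- c(cos(box$theta), sin(box$theta))
  v <- c(-u[2], u[1])
  pu <- poly %*% u; pv <- poly %*% v
  w <- max(pu) - min(pu); h <- max(pv) - min(pv)
  if (w <= 1e-9 || h <= 1e-9) return(NULL)
  cu <- (max(pu) + min(pu)) / 2; cv <- (max(pv) + min(pv)) / 2
  rotated_box(cu * u[1] + cv * v[1], cu * u[2] + cv * v[2], w, h, box$theta)
}

#' Mosaic augmentation of four annotated images
#'
#' Composes four annotated sources into one training composite: a junction
#' point is sampled uniformly in the central 50% of a `2*side` canvas; each
#' source is uniformly scaled to cover its junction quadrant, anchored at the
#' junction, with overflow clipped at the quadrant boundary; the canvas is
#' then resized back to `side`. Ground-truth boxes follow each source's
#' affine map; boxes whose centers leave their quadrant are dropped, and
#' surviving boxes are clipped in extent (angle preserved).
#'
#' @param scenes List of exactly 4 annotated sources, each a list with
#'   `image` (grey matrix), `boxes` (list of [rotated_box()]) and optionally
#'   `id`.
#' @param side Output square side (default 640).
#' @param seed Integer seed; the same seed reproduces the composite exactly.
#' @param junction Optional fixed junction point (canvas coordinates, i.e. in
#'   `[0, 2*side]^2`) overriding the random draw.
#' @param fill Background grey.
#' @return A list of class `mosaic_result`: `image` (side x side), `boxes`
#'   (clipped, output coordinates), `boxes_unclipped`, `box_source` (source
#'   index per surviving box), `sources`, `center` (junction in output
#'   coordinates), `transforms` (per-source scale/origin on the canvas, plus
#'   the final canvas-to-output scale).
#' @export
mosaic_augment <- function(scenes, side = 640L, seed = 1L, junction = NULL,
                           fill = .FILL_GREY) {
  if (!is.list(scenes) || length(scenes) != 4L) {
    stop("mosaic requires exactly 4 annotated images")
  }
  side <- as.integer(side)
  s2 <- 2L * side
  j <- if (is.null(junction)) {
    with_seed(seed, stats::runif(2, min = 0.5 * s2 * 0.5, max = 1.5 * side))
  } else junction
  jx <- j[1]; jy <- j[2]
  canvas <- matrix(fill, nrow = s2, ncol = s2)
  # quadrant windows (x0, x1, y0, y1), junction-anchored corner per quadrant
  quads <- list(
    list(win = c(0, jx, 0, jy),   anchor = c("right", "bottom")), # top-left
    list(win = c(jx, s2, 0, jy),  anchor = c("left", "bottom")),  # top-right
    list(win = c(0, jx, jy, s2),  anchor = c("right", "top")),    # bottom-left
    list(win = c(jx, s2, jy, s2), anchor = c("left", "top"))      # bottom-right
  )
  transforms <- vector("list", 4L)
  boxes <- list(); boxes_unclipped <- list(); box_source <- integer(0)
  for (k in 1:4) {
    src <- scenes[[k]]
    img <- as_grey_matrix(src$image)
    w <- img_width(img); h <- img_height(img)
    win <- quads[[k]]$win
    rw <- win[2] - win[1]; rh <- win[4] - win[3]
    if (rw < 1 || rh < 1) { transforms[[k]] <- list(scale = NA, origin = c(NA, NA)); next }
    f <- max(rw / w, rh / h) # cover the quadrant
    x0c <- if (quads[[k]]$anchor[1] == "right") jx - w * f else jx
    y0c <- if (quads[[k]]$anchor[2] == "bottom") jy - h * f else jy
    transforms[[k]] <- list(scale = f, origin = c(x0c, y0c))
    # paint the quadrant window from the scaled source
    cx0 <- as.integer(floor(win[1])) + 1L; cx1 <- as.integer(ceiling(win[2]))
    ry0 <- as.integer(floor(win[3])) + 1L; ry1 <- as.integer(ceiling(win[4]))
    cx1 <- min(cx1, s2); ry1 <- min(ry1, s2)
    xo <- rep(seq(cx0, cx1) - 0.5, each = ry1 - ry0 + 1L)
    yo <- rep(seq(ry0, ry1) - 0.5, times = cx1 - cx0 + 1L)
    vals <- bilinear_sample(img, (xo - x0c) / f, (yo - y0c) / f, fill)
    canvas[ry0:ry1, cx0:cx1] <- matrix(vals, nrow = ry1 - ry0 + 1L)
    for (b in as_box_list(src$boxes)) {
      tb <- rotated_box(b$cx * f + x0c, b$cy * f + y0c, b$w * f, b$h * f, b$theta)
      inside <- tb$cx >= win[1] && tb$cx <= win[2] && tb$cy >= win[3] && tb$cy <= win[4]
      if (!inside) {
        log_event("mosaic: dropped box from source %d (center outside quadrant)", k)
        next
      }
      cb <- clip_box_to_rect(tb, win[1], win[2], win[3], win[4])
      if (is.null(cb)) next
      boxes_unclipped[[length(boxes_unclipped) + 1L]] <- tb
      boxes[[length(boxes) + 1L]] <- cb
      box_source <- c(box_source, k)
    }
  }
  # resize canvas 2*side -> side
  out <- affine_resample(canvas, A = diag(2) * 2, b = c(0, 0),
                         out_w = side, out_h = side, fill = fill)
  half <- function(b) rotated_box(b$cx / 2, b$cy / 2, b$w / 2, b$h / 2, b$theta)
  structure(
    list(image = out,
         boxes = lapply(boxes, half),
         boxes_unclipped = lapply(boxes_unclipped, half),
         box_source = box_source,
         sources = vapply(seq_along(scenes), function(k) {
           id <- scenes[[k]]$id
           if (is.null(id)) sprintf("source_%d", k) else as.character(id)
         }, character(1)),
         center = c(jx, jy) / 2,
         transforms = transforms,
         final_scale = 0.5,
         seed = seed),
    class = "mosaic_result"
  )
}

#' Random photometric and stretch augmentation
#'
#' Applies, in order: an anisotropic stretch (independent x/y resize factors),
#' a Gaussian blur, and a contrast scaling about mid-grey, with all three
#' parameters drawn uniformly from their configured ranges under the given
#' seed. Degenerate ranges (`c(1, 1)` stretch/contrast, `c(0, 0)` blur) leave
#' the image untouched. Because an anisotropic stretch does not map a rotated
#' rectangle to a rectangle, boxes are re-fit as the minimum-area rotated box
#' of their stretched corners.
#'
#' @param image Grey image matrix.
#' @param boxes Optional list of [rotated_box()]es.
#' @param seed Integer seed.
#' @param stretch_range Range of per-axis stretch factors (default
#'   `c(0.9, 1.1)`).
#' @param blur_sigma_range Range of the blur standard deviation in pixels
#'   (default `c(0, 1.5)`).
#' @param contrast_range Range of the contrast factor (default
#'   `c(0.85, 1.15)`).
#' @return A list: `image`, `boxes`, `params` (the sampled `sx`, `sy`,
#'   `sigma`, `contrast`).
#' @export
random_photometric <- function(image, boxes = list(), seed = 1L,
                               stretch_range = c(0.9, 1.1),
                               blur_sigma_range = c(0, 1.5),
                               contrast_range = c(0.85, 1.15)) {
  image <- as_grey_matrix(image)
  pars <- with_seed(seed, list(
    sx = stats::runif(1, stretch_range[1], stretch_range[2]),
    sy = stats::runif(1, stretch_range[1], stretch_range[2]),
    sigma = stats::runif(1, blur_sigma_range[1], blur_sigma_range[2]),
    contrast = stats::runif(1, contrast_range[1], contrast_range[2])
  ))
  out <- image
  boxes <- as_box_list(boxes)
  if (abs(pars$sx - 1) > 1e-12 || abs(pars$sy - 1) > 1e-12) {
    w <- img_width(image); h <- img_height(image)
    nw <- max(1L, as.integer(round(w * pars$sx)))
    nh <- max(1L, as.integer(round(h * pars$sy)))
    fx <- nw / w; fy <- nh / h # realized factors after rounding
    out <- affine_resample(image, A = diag(c(1 / fx, 1 / fy)), b = c(0, 0),
                           out_w = nw, out_h = nh)
    boxes <- lapply(boxes, function(b) {
      crn <- box_corners(b)
      min_area_box(cbind(crn[, 1] * fx, crn[, 2] * fy))
    })
    pars$sx <- fx; pars$sy <- fy
  }
  if (pars$sigma > 1e-8) {
    out <- as.matrix(EBImage::gblur(out, sigma = pars$sigma))
  }
  if (abs(pars$contrast - 1) > 1e-12) {
    out <- pmin(pmax(0.5 + (out - 0.5) * pars$contrast, 0), 1)
  }
  list(image = out, boxes = boxes, params = pars)
}
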