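# Procedural face-like scenes with exact ground-truth eye-region boxes, and a
# classical blob-pairing baseline detector, so the detect -> QA -> crop ->
# evaluate pipeline can run end to end without trained weights.
#
# Scene geometry is parameterized by the eye height h_e: the two eyes (bright
# sclera ellipse + dark iris disc) sit at +/- s/2 along the tilted inter-eye
# axis with s = 3.2 * h_e; the ground-truth box pads the two-eye hull by 25%
# of the inter-eye span horizontally and 40% of the eye height vertically,
# giving box sides w = 6.4 * h_e, h = 1.8 * h_e. The target area fraction
# then fixes h_e = sqrt(af * W * H / 11.52).

.EYE_SPAN_FACTOR <- 3.2   # inter-eye center distance in units of eye height
.EYE_WIDTH_FACTOR <- 1.6  # sclera width in units of eye height
.IRIS_RADIUS_FACTOR <- 0.32
.BOX_W_FACTOR <- 6.4      # = 1.5 * span + eye width
.BOX_H_FACTOR <- 1.8      # = eye height * (1 + 2 * 0.4)

#' Specification of a synthetic face scene
#'
#' Captures the generation parameters of one scene. Defaults emulate the
#' observed clinical distributions: tilt (the ocular alignment angle) within
#' `[-15, 15]` degrees and eye-region area fraction within `[0.022, 0.305]`
#' of the frame.
#'
#' @param image_size `c(width, height)` in pixels (default 960 x 720).
#' @param tilt Inter-eye axis angle versus horizontal, in degrees.
#' @param area_fraction Target eye-region fraction of the frame.
#' @param occlusion One of `"none"`, `"bar"` (a bright swab-like bar) or
#'   `"blob"` (a finger-like dark ellipse).
#' @param occluder_position Occluder center in the tilted face frame, in
#'   pixels relative to the box center; default sits on the lower half of
#'   one eye.
#' @param noise_sd Additive Gaussian noise standard deviation in grey levels
#'   (0-255 scale).
#' @param seed Integer seed for the scene's randomness (noise, occluder
#'   jitter).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(960L, 720L), tilt = 0,
                       area_fraction = 0.134,
                       occlusion = c("none", "bar", "blob"),
                       occluder_position = NULL,
                       noise_sd = 6, seed = 1L) {
  occlusion <- match.arg(occlusion)
  stopifnot(length(image_size) == 2L, all(image_size >= 64),
            is.finite(tilt), area_fraction > 0, area_fraction < 1,
            noise_sd >= 0)
  structure(
    list(image_size = as.integer(image_size), tilt = as.numeric(tilt),
         area_fraction = as.numeric(area_fraction), occlusion = occlusion,
         occluder_position = occluder_position,
         noise_sd = as.numeric(noise_sd), seed = as.integer(seed)),
    class = "scene_spec"
  )
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec> %dx%d  tilt %.2f deg  area %.3f  occlusion %s  noise_sd %.1f  seed %d\n",
              x$image_size[1], x$image_size[2], x$tilt, x$area_fraction,
              x$occlusion, x$noise_sd, x$seed))
  invisible(x)
}

#' Generate a synthetic face scene
#'
#' Renders a skin-toned face oval on a darker backdrop with two eyes (bright
#' sclera ellipse enclosing a dark iris disc), brows and a mouth, all rotated
#' by the requested tilt about the face center; optionally paints an occluder
#' and adds seeded Gaussian noise. The exact ground-truth rotated box around
#' both eyes (with the fixed periocular pad) is returned alongside.
#'
#' @param spec A [scene_spec()].
#' @return A list of class `synthetic_scene`: `image` (grey matrix), `truth`
#'   (the ground-truth [rotated_box()]), `spec`.
#' @examples
#' sc <- generate_scene(scene_spec(tilt = 8, area_fraction = 0.1, seed = 3))
#' sc$truth
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  W <- spec$image_size[1]; H <- spec$image_size[2]
  he <- sqrt(spec$area_fraction * W * H / (.BOX_W_FACTOR * .BOX_H_FACTOR))
  bw <- .BOX_W_FACTOR * he; bh <- .BOX_H_FACTOR * he
  th <- spec$tilt * pi / 180
  # the rotated truth box must fit inside the frame
  ex <- (abs(bw * cos(th)) + abs(bh * sin(th))) / 2
  ey <- (abs(bw * sin(th)) + abs(bh * cos(th))) / 2
  if (ex > W / 2 || ey > H / 2) {
    stop(sprintf(
      "area_fraction %.3f with tilt %.1f deg does not fit a %dx%d frame",
      spec$area_fraction, spec$tilt, W, H))
  }
  cx <- W / 2; cy <- H / 2
  ct <- cos(th); st <- sin(th)
  X <- matrix(rep(seq_len(W) - 0.5, each = H), nrow = H)
  Y <- matrix(rep(seq_len(H) - 0.5, times = W), nrow = H)
  # face-frame coordinates (u along the inter-eye axis, v across it)
  U <- (X - cx) * ct + (Y - cy) * st
  V <- -(X - cx) * st + (Y - cy) * ct
  img <- matrix(0.35, H, W) # backdrop
  inside_ellipse <- function(u0, v0, a, b) ((U - u0) / a)^2 + ((V - v0) / b)^2 <= 1
  # face oval with a soft vertical shading
  face <- inside_ellipse(0, 0.6 * he, 3.9 * he, 5.2 * he)
  img[face] <- 0.78 - 0.04 * (V[face] / (5.2 * he))
  s <- .EYE_SPAN_FACTOR * he
  for (side in c(-1, 1)) {
    u0 <- side * s / 2
    img[inside_ellipse(u0, -1.05 * he, 0.85 * he, 0.13 * he)] <- 0.50       # brow
    img[inside_ellipse(u0, 0, 0.8 * he, 0.5 * he)] <- 0.95                  # sclera
    img[inside_ellipse(u0, 0, .IRIS_RADIUS_FACTOR * he, .IRIS_RADIUS_FACTOR * he)] <- 0.10 # iris
  }
  img[inside_ellipse(0, 2.6 * he, 1.1 * he, 0.25 * he)] <- 0.55             # mouth
  if (spec$occlusion != "none") {
    pos <- spec$occluder_position
    if (is.null(pos)) pos <- c(s / 2, 0.30 * he) # lower half of one eye
    if (spec$occlusion == "bar") {
      # bright swab-like bar, slightly rotated in the face frame
      ang <- 25 * pi / 180
      du <- (U - pos[1]) * cos(ang) + (V - pos[2]) * sin(ang)
      dv <- -(U - pos[1]) * sin(ang) + (V - pos[2]) * cos(ang)
      img[abs(du) <= 1.5 * he & abs(dv) <= 0.22 * he] <- 0.92
    } else {
      img[inside_ellipse(pos[1], pos[2], 0.8 * he, 0.55 * he)] <- 0.35      # finger
    }
  }
  if (spec$noise_sd > 0) {
    img <- img + with_seed(spec$seed,
                           matrix(stats::rnorm(W * H, 0, spec$noise_sd / 255), H, W))
    img <- pmin(pmax(img, 0), 1)
  }
  structure(
    list(image = img,
         truth = rotated_box(cx, cy, bw, bh, th),
         spec = spec),
    class = "synthetic_scene"
  )
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %dx%d  truth %s\n",
              ncol(x$image), nrow(x$image), format(x$truth)))
  invisible(x)
}

#' Generate a reproducible synthetic dataset
#'
#' Samples scene specifications uniformly from the given ranges and renders
#' each scene; optionally writes, per scene, a PNG image plus roLabelImg XML
#' and YOLO-OBB annotation files. Fully reproducible from `seed`.
#'
#' @param n Number of scenes.
#' @param image_size Frame size `c(width, height)`.
#' @param tilt_range Degrees, sampled uniformly (default `c(-15, 15)`).
#' @param area_range Eye-region area fractions, sampled uniformly (default
#'   the observed clinical envelope `c(0.022, 0.305)`).
#' @param occlusion Occlusion types to sample from (default `"none"`).
#' @param noise_sd Noise level passed to every scene.
#' @param seed Master seed.
#' @param dir Output directory for `scene_####.png/.xml/.txt`; `NULL` keeps
#'   everything in memory.
#' @return A list of class `synthetic_dataset`: `scenes` (list of
#'   [generate_scene()] results) and `manifest` (data.frame of sampled
#'   parameters and any file paths).
#' @export
generate_dataset <- function(n, image_size = c(960L, 720L),
                             tilt_range = c(-15, 15),
                             area_range = c(0.022, 0.305),
                             occlusion = "none",
                             noise_sd = 6, seed = 1L, dir = NULL) {
  stopifnot(n >= 1)
  draws <- with_seed(seed, list(
    tilt = stats::runif(n, tilt_range[1], tilt_range[2]),
    area = stats::runif(n, area_range[1], area_range[2]),
    occ = sample(occlusion, n, replace = TRUE),
    sub_seed = sample.int(.Machine$integer.max - 1L, n)
  ))
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  scenes <- vector("list", n)
  paths <- character(n)
  for (i in seq_len(n)) {
    sp <- scene_spec(image_size = image_size, tilt = draws$tilt[i],
                     area_fraction = draws$area[i], occlusion = draws$occ[i],
                     noise_sd = noise_sd, seed = draws$sub_seed[i])
    scenes[[i]] <- generate_scene(sp)
    if (!is.null(dir)) {
      stem <- file.path(dir, sprintf("scene_%04d", i))
      write_image(scenes[[i]]$image, paste0(stem, ".png"))
      # store only the file name so the annotation files are relocatable
      ann <- annotated_image(basename(paste0(stem, ".png")), image_size,
                             list(scenes[[i]]$truth))
      write_rolabelimg(ann, paste0(stem, ".xml"))
      write_yolo_obb(ann, paste0(stem, ".txt"))
      paths[i] <- paste0(stem, ".png")
    }
  }
  structure(
    list(scenes = scenes,
         manifest = data.frame(
           index = seq_len(n), tilt = draws$tilt, area_fraction = draws$area,
           occlusion = draws$occ, seed = draws$sub_seed,
           path = if (is.null(dir)) NA_character_ else paths)),
    class = "synthetic_dataset"
  )
}

# per-label blob moments from a labelled mask; returns a data.frame
blob_moments <- function(labels, img) {
  idx <- which(labels > 0)
  if (!length(idx)) return(NULL)
  lab <- labels[idx]
  ys <- ((idx - 1L) %% nrow(labels)) + 1L
  xs <- ((idx - 1L) %/% nrow(labels)) + 1L
  area <- tabulate(lab)
  keep <- which(area > 0)
  cx <- rowsum(xs - 0.5, lab)[, 1] / area[keep]
  cy <- rowsum(ys - 0.5, lab)[, 1] / area[keep]
  names(cx) <- names(cy) <- keep
  mxx <- rowsum((xs - 0.5)^2, lab)[, 1] / area[keep] - cx^2
  myy <- rowsum((ys - 0.5)^2, lab)[, 1] / area[keep] - cy^2
  mxy <- rowsum((xs - 0.5) * (ys - 0.5), lab)[, 1] / area[keep] - cx * cy
  tr <- mxx + myy
  dt <- pmax(mxx * myy - mxy^2, 0)
  l1 <- tr / 2 + sqrt(pmax(tr^2 / 4 - dt, 0))
  l2 <- tr / 2 - sqrt(pmax(tr^2 / 4 - dt, 0))
  ecc <- sqrt(pmax(1 - l2 / pmax(l1, 1e-12), 0))
  intensity <- rowsum(img[idx], lab)[, 1] / area[keep]
  data.frame(label = keep, area = area[keep], cx = cx, cy = cy,
             ecc = ecc, intensity = intensity)
}

#' Classical baseline eye-region detector
#'
#' A non-neural stand-in detector used as a test fixture for the pipeline:
#' dark blobs are segmented with an adaptive threshold and connected-component
#' labelling, filtered by area and eccentricity (irises are small, dark and
#' round), and the most plausible pair is selected by size symmetry and
#' separation-to-radius ratio. The inter-center line gives the box angle; the
#' box itself is rebuilt from the pair with the same periocular pad the
#' generator uses. The confidence heuristic combines pair symmetry, blob
#' roundness, blob contrast and separation plausibility.
#'
#' @param image Grey image matrix.
#' @param image_id Identifier attached to the returned [detection()].
#' @return A [detection()], or `NULL` when fewer than two candidate blobs are
#'   found (feeding the QA "unreliable" path).
#' @export
detect_eyes_baseline <- function(image, image_id = "img") {
  img <- as_grey_matrix(image)
  lo <- stats::quantile(img, 0.002, names = FALSE)
  med <- stats::median(img)
  thr <- lo + 0.30 * (med - lo)
  mask <- img < thr
  if (!any(mask)) return(NULL)
  labels <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(img), ncol(img)))
  blobs <- blob_moments(labels, img)
  if (is.null(blobs)) return(NULL)
  npx <- length(img)
  blobs <- blobs[blobs$area >= 25 & blobs$area <= 0.03 * npx & blobs$ecc <= 0.85, ]
  if (nrow(blobs) < 2L) return(NULL)
  blobs <- blobs[order(-blobs$area), ][seq_len(min(10L, nrow(blobs))), ]
  best <- NULL
  for (i in seq_len(nrow(blobs) - 1L)) {
    for (j in (i + 1L):nrow(blobs)) {
      a1 <- blobs$area[i]; a2 <- blobs$area[j]
      sym <- min(a1, a2) / max(a1, a2)
      d <- sqrt((blobs$cx[i] - blobs$cx[j])^2 + (blobs$cy[i] - blobs$cy[j])^2)
      rbar <- (sqrt(a1 / pi) + sqrt(a2 / pi)) / 2
      # iris radius is 0.32 h_e and the span 3.2 h_e: d / rbar should be ~10
      sep <- exp(-(((d / rbar) - .EYE_SPAN_FACTOR / .IRIS_RADIUS_FACTOR) / 4)^2)
      score <- sym * sep
      if (is.null(best) || score > best$score) {
        best <- list(i = i, j = j, score = score, sym = sym, sep = sep, d = d,
                     rbar = rbar)
      }
    }
  }
  i <- best$i; j <- best$j
  dx <- blobs$cx[j] - blobs$cx[i]; dy <- blobs$cy[j] - blobs$cy[i]
  angle <- normalize_angle(atan2(dy, dx))
  he <- best$rbar / .IRIS_RADIUS_FACTOR
  span <- best$d
  box <- rotated_box(
    (blobs$cx[i] + blobs$cx[j]) / 2, (blobs$cy[i] + blobs$cy[j]) / 2,
    1.5 * span + .EYE_WIDTH_FACTOR * he, .BOX_H_FACTOR * he, angle)
  roundness <- 1 - mean(blobs$ecc[c(i, j)])
  contrast <- min(1, max(0, (med - mean(blobs$intensity[c(i, j)])) / 0.5))
  conf <- min(1, max(0, 0.25 * best$sym + 0.25 * roundness +
                       0.25 * contrast + 0.25 * best$sep))
  detection(box, conf, image_id)
}
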