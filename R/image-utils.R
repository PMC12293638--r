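# In-memory images are plain numeric matrices in [0, 1], indexed [row = y,
# col = x] with x rightward and y downward. Continuous coordinates put pixel
# (i, j) at center (j - 0.5, i - 0.5), covering [j-1, j] x [i-1, i], so an
# image of width W spans x in [0, W].

# default pad/fill grey used by letterboxing, mosaic and deskew cropping
.FILL_GREY <- 114 / 255

img_width <- function(img) ncol(img)
img_height <- function(img) nrow(img)

as_grey_matrix <- function(img) {
  if (is.matrix(img)) return(img)
  if (is.array(img) && length(dim(img)) == 3L) {
    # average color channels
    return(apply(img[, , seq_len(min(3L, dim(img)[3])), drop = FALSE], c(1, 2), mean))
  }
  stop("expected a numeric matrix (grey) or HxWxC array (color)")
}

# Bilinear sample of img at continuous coords (xs, ys); outside -> fill.
bilinear_sample <- function(img, xs, ys, fill = .FILL_GREY) {
  h <- nrow(img); w <- ncol(img)
  fx <- xs - 0.5 # 0-based center-index space
  fy <- ys - 0.5
  x0 <- floor(fx); y0 <- floor(fy)
  tx <- fx - x0; ty <- fy - y0
  # neighbor column/row indices, 1-based; clamp for lookup, mask for fill
  cx0 <- pmin(pmax(x0 + 1L, 1L), w); cx1 <- pmin(pmax(x0 + 2L, 1L), w)
  ry0 <- pmin(pmax(y0 + 1L, 1L), h); ry1 <- pmin(pmax(y0 + 2L, 1L), h)
  v00 <- img[cbind(ry0, cx0)]; v01 <- img[cbind(ry0, cx1)]
  v10 <- img[cbind(ry1, cx0)]; v11 <- img[cbind(ry1, cx1)]
  out <- (1 - ty) * ((1 - tx) * v00 + tx * v01) + ty * ((1 - tx) * v10 + tx * v11)
  outside <- xs < 0 | xs > w | ys < 0 | ys > h
  out[outside] <- fill
  out
}

# Resample img into an out_h x out_w image where output continuous coords map
# to input coords via (x_in, y_in) = A %*% (x_out, y_out) + b.
affine_resample <- function(img, A, b, out_w, out_h, fill = .FILL_GREY) {
  xo <- rep(seq_len(out_w) - 0.5, each = out_h)
  yo <- rep(seq_len(out_h) - 0.5, times = out_w)
  xi <- A[1, 1] * xo + A[1, 2] * yo + b[1]
  yi <- A[2, 1] * xo + A[2, 2] * yo + b[2]
  matrix(bilinear_sample(img, xi, yi, fill), nrow = out_h, ncol = out_w)
}

# run expr with a fixed RNG seed, restoring the caller's RNG state after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Read a PNG image as a grey matrix
#'
#' @param path PNG file path.
#' @return Numeric matrix in `[0, 1]`, rows = y (top down), cols = x.
#' @export
read_image <- function(path) {
  as_grey_matrix(png::readPNG(path))
}

#' Write a grey image matrix to PNG
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}
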