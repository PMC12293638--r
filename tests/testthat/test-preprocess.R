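checkerboard <- function(n = 64, cell = 8) {
  idx <- (outer(seq_len(n) - 1, seq_len(n) - 1, "+") %/% cell) %% 2
  matrix(as.numeric(idx), n, n)
}

test_that("letterbox arithmetic matches the uniform-scale rule", {
  sq <- matrix(runif(500 * 500), 500, 500)
  lb <- letterbox(sq, side = 640)
  expect_equal(lb$scale, 1.28)
  expect_equal(unname(lb$pad), c(0, 0, 0, 0))
  expect_equal(dim(lb$image), c(640, 640))

  wide <- matrix(runif(720 * 1280), 720, 1280)
  lb <- letterbox(wide, side = 640)
  expect_equal(lb$scale, 0.5)
  expect_equal(unname(lb$pad), c(0, 140, 0, 140))
  # pad rows filled with the letterbox grey
  expect_true(all(lb$image[1:140, ] == 114 / 255))
  expect_true(all(lb$image[501:640, ] == 114 / 255))
})

test_that("letterbox transforms boxes affinely and round-trips within 0.5 px", {
  wide <- matrix(0.5, 720, 1280)
  b <- rotated_box(100, 100, 50, 20, 0.1)
  lb <- letterbox(wide, list(b), side = 640)
  tb <- lb$boxes[[1]]
  expect_equal(c(tb$cx, tb$cy, tb$w, tb$h, tb$theta), c(50, 190, 25, 10, 0.1))
  back <- letterbox_unmap_box(lb, tb)
  expect_lt(abs(back$cx - b$cx), 0.5)
  expect_lt(abs(back$cy - b$cy), 0.5)
  expect_box_equal(back, b, tol = 1e-9)
})

test_that("letterbox preserves content up to resampling", {
  img <- matrix(0, 100, 200)
  img[40:60, 90:110] <- 1 # bright block in the middle
  lb <- letterbox(img, side = 100)
  # block center maps to image center; check a bright pixel there
  expect_gt(lb$image[50, 50], 0.9)
  expect_error(letterbox(matrix(numeric(0), 0, 0)), "zero-size")
})

test_that("mosaic with a centered junction places identical boxes at quadrant centers", {
  img <- matrix(0.5, 200, 200)
  ctr_box <- rotated_box(100, 100, 60, 30, 0.2)
  scenes <- lapply(1:4, function(k) list(image = img, boxes = list(ctr_box),
                                         id = sprintf("p%d", k)))
  side <- 320
  mr <- mosaic_augment(scenes, side = side, junction = c(side, side))
  expect_equal(length(mr$boxes), 4L)
  expect_equal(dim(mr$image), c(side, side))
  centers <- t(vapply(mr$boxes, function(b) c(b$cx, b$cy), numeric(2)))
  want <- rbind(c(1, 1), c(3, 1), c(1, 3), c(3, 3)) * side / 4
  ord <- order(round(centers[, 2], 3), round(centers[, 1], 3))
  expect_equal(centers[ord, ], want[order(want[, 2], want[, 1]), ],
               tolerance = 1e-6)
  expect_equal(mr$sources, sprintf("p%d", 1:4))
})

test_that("mosaic is deterministic in its seed and validates input count", {
  set.seed(99)
  img <- matrix(runif(150 * 120), 150, 120)
  scenes <- lapply(1:4, function(k) {
    list(image = img, boxes = list(rotated_box(60, 75, 40, 20, 0.1)))
  })
  m1 <- mosaic_augment(scenes, side = 128, seed = 7)
  m2 <- mosaic_augment(scenes, side = 128, seed = 7)
  expect_identical(m1$image, m2$image)
  expect_equal(m1$center, m2$center)
  m3 <- mosaic_augment(scenes, side = 128, seed = 8)
  expect_false(isTRUE(all.equal(m1$center, m3$center)))
  expect_error(mosaic_augment(scenes[1:3], side = 128), "exactly 4")
})

test_that("mosaic boxes are affine images of their source boxes before clipping", {
  set.seed(101)
  imgs <- lapply(1:4, function(k) matrix(runif(100 * 160), 100, 160))
  box <- rotated_box(80, 50, 36, 18, -0.25)
  scenes <- lapply(imgs, function(im) list(image = im, boxes = list(box)))
  mr <- mosaic_augment(scenes, side = 256, seed = 5)
  expect_gt(length(mr$boxes_unclipped), 0L)
  for (k in seq_along(mr$boxes_unclipped)) {
    src <- mr$box_source[k]
    tf <- mr$transforms[[src]]
    want <- (box_corners(box) * tf$scale +
               matrix(tf$origin, 4, 2, byrow = TRUE)) * mr$final_scale
    got <- box_corners(mr$boxes_unclipped[[k]])
    # compare as point sets (corner order may differ by cyclic shift)
    d <- vapply(seq_len(4), function(i) {
      min(sqrt(rowSums((want - matrix(got[i, ], 4, 2, byrow = TRUE))^2)))
    }, numeric(1))
    expect_lt(max(d), 1e-6)
    # clipped survivor keeps the angle of its unclipped parent
    dth <- abs(normalize_angle(mr$boxes[[k]]$theta - mr$boxes_unclipped[[k]]$theta))
    expect_lt(min(dth, pi - dth), 1e-9)
  }
})

test_that("photometric augmentation with degenerate ranges is the identity", {
  img <- matrix(runif(80 * 60), 80, 60)
  out <- random_photometric(img, seed = 3, stretch_range = c(1, 1),
                            blur_sigma_range = c(0, 0), contrast_range = c(1, 1))
  expect_identical(out$image, img)
})

test_that("photometric augmentation is a pure function of input and seed", {
  img <- matrix(runif(80 * 60), 80, 60)
  a <- random_photometric(img, seed = 11)
  b <- random_photometric(img, seed = 11)
  expect_identical(a$image, b$image)
  expect_identical(a$params, b$params)
  c <- random_photometric(img, seed = 12)
  expect_false(identical(a$params, c$params))
})

test_that("blur halves high-frequency energy on a checkerboard", {
  img <- checkerboard(64, 8)
  blur2 <- random_photometric(img, seed = 1, stretch_range = c(1, 1),
                              blur_sigma_range = c(2, 2),
                              contrast_range = c(1, 1))$image
  hf_energy <- function(x) {
    f <- Mod(stats::fft(x - mean(x)))^2
    n <- nrow(x)
    freq <- pmin(0:(n - 1), n - (0:(n - 1))) / n
    hf <- outer(freq, freq, function(a, b) pmax(a, b) > 0.1)
    sum(f[hf])
  }
  expect_lt(hf_energy(blur2), 0.5 * hf_energy(img))
})

test_that("anisotropic stretch re-fits boxes through their mapped corners", {
  img <- matrix(runif(100 * 100), 100, 100)
  b0 <- rotated_box(50, 50, 40, 20, 0)
  out <- random_photometric(img, list(b0), seed = 2,
                            stretch_range = c(2, 2), blur_sigma_range = c(0, 0),
                            contrast_range = c(1, 1))
  # both axes doubled: axis-aligned box simply scales
  tb <- out$boxes[[1]]
  expect_box_equal(tb, rotated_box(100, 100, 80, 40, 0), tol = 1e-9)
  # rotated box under a non-uniform stretch: corners must still be enclosed
  b1 <- rotated_box(50, 50, 40, 20, 0.6)
  out <- random_photometric(img, list(b1), seed = 2,
                            stretch_range = c(0.9, 1.4),
                            blur_sigma_range = c(0, 0), contrast_range = c(1, 1))
  sx <- out$params$sx; sy <- out$params$sy
  mapped <- cbind(box_corners(b1)[, 1] * sx, box_corners(b1)[, 2] * sy)
  crn <- box_corners(out$boxes[[1]])
  expect_true(all(periocrop:::points_in_convex(mapped, crn, eps = 1e-6)))
})
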