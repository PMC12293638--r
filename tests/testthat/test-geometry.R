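test_that("box corners match closed forms and round-trip through re-fit", {
  crn <- box_corners(rotated_box(0, 0, 2, 1, 0))
  expect_equal(sort(crn[, 1]), c(-1, -1, 1, 1))
  expect_equal(sort(crn[, 2]), c(-0.5, -0.5, 0.5, 0.5))
  expect_equal(colMeans(crn), c(x = 0, y = 0))

  # quarter turn swaps the extents
  crn <- box_corners(rotated_box(0, 0, 2, 1, pi / 2))
  expect_equal(sort(crn[, 1]), c(-0.5, -0.5, 0.5, 0.5))
  expect_equal(sort(crn[, 2]), c(-1, -1, 1, 1))

  # 45-degree unit square: corners on the axes through the center
  crn <- box_corners(rotated_box(1, 1, 1, 1, pi / 4))
  d <- sqrt(2) / 2
  got <- crn[order(crn[, 1], crn[, 2]), ]
  want <- rbind(c(1 - d, 1), c(1, 1 - d), c(1, 1 + d), c(1 + d, 1))
  expect_equal(unname(got), want, tolerance = 1e-12)

  set.seed(42)
  for (i in 1:50) {
    b <- random_box()
    expect_box_equal(corners_to_box(box_corners(b)), b, tol = 1e-9)
  }
})

test_that("corner expansion is counterclockwise with centroid at the center", {
  set.seed(7)
  for (i in 1:20) {
    b <- random_box()
    crn <- box_corners(b)
    expect_equal(unname(colMeans(crn)), c(b$cx, b$cy), tolerance = 1e-12)
    # consistent cross-product sign around the loop
    n <- 4L
    cr <- vapply(1:n, function(k) {
      e1 <- crn[(k %% n) + 1L, ] - crn[k, ]
      e2 <- crn[((k + 1L) %% n) + 1L, ] - crn[(k %% n) + 1L, ]
      e1[1] * e2[2] - e1[2] * e2[1]
    }, numeric(1))
    expect_true(all(cr > 0) || all(cr < 0))
  }
})

test_that("intersection point sets cover identity, disjoint and octagon cases", {
  sq <- box_corners(rotated_box(0, 0, 1, 1, 0))
  # identical squares: the 4 shared vertices
  pts <- intersection_points(sq, sq)
  expect_equal(nrow(pts), 4L)
  # disjoint squares: empty set
  far <- box_corners(rotated_box(2, 0, 1, 1, 0))
  expect_equal(nrow(intersection_points(sq, far)), 0L)
  # unit square vs its 45-degree rotation: 8 octagon points
  rot <- box_corners(rotated_box(0, 0, 1, 1, pi / 4))
  pts <- intersection_points(sq, rot)
  expect_equal(nrow(pts), 8L)
  # cross-check each point against brute-force segment enumeration: all
  # points must lie on the boundary of both squares
  on_boundary <- function(p, half) {
    (abs(abs(p[1]) - half) < 1e-9 && abs(p[2]) <= half + 1e-9) ||
      (abs(abs(p[2]) - half) < 1e-9 && abs(p[1]) <= half + 1e-9)
  }
  for (k in seq_len(nrow(pts))) expect_true(on_boundary(pts[k, ], 0.5))
})

test_that("convex sorting orders points counterclockwise and handles degeneracy", {
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  set.seed(3)
  shuffled <- sq[sample(4), ]
  sorted <- convex_sort(shuffled)
  expect_equal(polygon_area(sorted), 1)
  # 3 collinear points: zero-area polygon
  col3 <- matrix(c(0, 0, 1, 1, 2, 2), ncol = 2, byrow = TRUE)
  expect_equal(polygon_area(convex_sort(col3)), 0)
  # octagon points in random order match the convex hull ordering
  ang <- (0:7) * pi / 4 + pi / 8
  oct <- cbind(cos(ang), sin(ang))
  perm <- oct[sample(8), ]
  sorted <- convex_sort(perm)
  hull_order <- perm[grDevices::chull(perm), ]
  expect_equal(polygon_area(sorted), polygon_area(hull_order), tolerance = 1e-12)
  expect_equal(nrow(sorted), 8L)
})

test_that("fan-triangulated area equals closed forms", {
  tri <- matrix(c(0, 0, 1, 0, 0, 1), ncol = 2, byrow = TRUE)
  expect_equal(polygon_area(tri), 0.5)
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  expect_equal(polygon_area(sq), 1)
  ang <- (0:5) * pi / 3
  hexa <- cbind(cos(ang), sin(ang))
  expect_equal(polygon_area(hexa), 3 * sqrt(3) / 2, tolerance = 1e-12)
  expect_equal(polygon_area(sq[1:2, ]), 0) # < 3 vertices
})

test_that("skew IOU matches closed-form cases", {
  a <- rotated_box(0, 0, 1, 1, 0)
  expect_equal(skew_iou(a, a), 1)
  expect_equal(skew_iou(a, rotated_box(0.5, 0, 1, 1, 0)), 1 / 3,
               tolerance = 1e-12)
  # unit square vs its 45-degree rotation: octagon area 2(sqrt(2)-1)
  oct_area <- 2 * (sqrt(2) - 1)
  expect_equal(skew_iou(a, rotated_box(0, 0, 1, 1, pi / 4)),
               oct_area / (2 - oct_area), tolerance = 1e-12)
})

test_that("skew IOU is symmetric, bounded, and exact for axis-aligned boxes", {
  set.seed(11)
  for (i in 1:100) {
    p <- random_box(); q <- random_box()
    ipq <- skew_iou(p, q)
    expect_equal(ipq, skew_iou(q, p), tolerance = 1e-12)
    expect_gte(ipq, 0); expect_lte(ipq, 1)
    # axis-aligned pair from the same draw: interval-overlap closed form
    p0 <- rotated_box(p$cx, p$cy, p$w, p$h, 0)
    q0 <- rotated_box(q$cx, q$cy, q$w, q$h, 0)
    expect_equal(skew_iou(p0, q0), aa_iou(p0, q0), tolerance = 1e-12)
  }
  # IOU 1 iff identical up to the representation symmetry
  b <- rotated_box(0.3, 0.4, 0.2, 0.1, 0.7)
  expect_equal(skew_iou(b, rotated_box(0.3, 0.4, 0.1, 0.2, 0.7 + pi / 2)), 1,
               tolerance = 1e-12)
  expect_lt(skew_iou(b, rotated_box(0.3, 0.4, 0.2, 0.1, 0.71)), 1)
})

test_that("skew IOU is invariant under shared rigid motions", {
  set.seed(23)
  for (i in 1:50) {
    p <- random_box(); q <- random_box()
    ang <- runif(1, -pi, pi); sh <- runif(2, -5, 5)
    p2 <- transform_box(p, ang, sh)
    q2 <- transform_box(q, ang, sh)
    expect_equal(skew_iou(p2, q2), skew_iou(p, q), tolerance = 1e-9)
  }
})

test_that("skew IOU agrees with the grid-sampling reference", {
  set.seed(5)
  for (i in 1:50) {
    p <- random_box(); q <- random_box()
    expect_equal(skew_iou(p, q), raster_iou(p, q, 800), tolerance = 1e-2)
  }
})

test_that("minimum-area box recovers rectangles and encloses point sets", {
  set.seed(17)
  for (i in 1:20) {
    b <- random_box()
    expect_box_equal(min_area_box(box_corners(b)), b, tol = 1e-9)
  }
  pts <- cbind(runif(30), runif(30))
  fit <- min_area_box(pts)
  crn <- box_corners(fit)
  expect_true(all(periocrop:::points_in_convex(pts, crn, eps = 1e-9)))
})

test_that("degenerate box parameters are rejected", {
  expect_error(rotated_box(0, 0, 0, 1), "w")
  expect_error(rotated_box(0, 0, 1, -2), "w")
  expect_error(rotated_box(NA, 0, 1, 1))
})
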