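test_that("box-to-Gaussian map gives the uniform-rectangle covariance", {
  g <- box_to_gaussian(rotated_box(0, 0, 2, 1, 0))
  expect_equal(c(g$a, g$b, g$c), c(1 / 3, 1 / 12, 0))
  g <- box_to_gaussian(rotated_box(0, 0, 2, 1, pi / 2))
  expect_equal(c(g$a, g$b, g$c), c(1 / 12, 1 / 3, 0), tolerance = 1e-12)
  # squares are rotation-invariant
  for (th in c(0, 0.3, 1.1, -0.7)) {
    g <- box_to_gaussian(rotated_box(5, -2, 1, 1, th))
    expect_equal(c(g$a, g$b, g$c), c(1 / 12, 1 / 12, 0), tolerance = 1e-12)
    expect_equal(c(g$x, g$y), c(5, -2))
  }
})

test_that("gaussian_box rejects non-positive-definite covariances", {
  expect_error(gaussian_box(0, 0, -1, 1), "positive-definite")
  expect_error(gaussian_box(0, 0, 1, 1, c = 1.5), "positive-definite")
  expect_silent(gaussian_box(0, 0, 1, 1, c = 0.5))
})

test_that("Bhattacharyya terms match hand-evaluated closed forms", {
  g <- gaussian_box(0.2, -0.3, 0.05, 0.02, 0.01)
  bt <- bhattacharyya_terms(g, g)
  expect_equal(bt$B1, 0)
  expect_equal(bt$B2, 0)
  expect_equal(bt$BD, 0)

  # unit squares one width apart: B1 = 1.5, B2 = 0
  bt <- bhattacharyya_terms(gaussian_box(0, 0, 1 / 12, 1 / 12),
                            gaussian_box(1, 0, 1 / 12, 1 / 12))
  expect_equal(bt$B1, 1.5, tolerance = 1e-12)
  expect_equal(bt$B2, 0, tolerance = 1e-12)

  # same center, different shapes: pure B2 = log(5/4)/2
  bt <- bhattacharyya_terms(gaussian_box(0, 0, 1 / 12, 1 / 12),
                            gaussian_box(0, 0, 1 / 3, 1 / 12))
  expect_equal(bt$B1, 0)
  expect_equal(bt$B2, 0.5 * log(5 / 4), tolerance = 1e-12)
})

test_that("Bhattacharyya terms agree with numeric integration on sampled pairs", {
  set.seed(31)
  for (i in 1:10) {
    g1 <- box_to_gaussian(random_box())
    g2 <- box_to_gaussian(random_box())
    bd_closed <- bhattacharyya_terms(g1, g2)$BD
    expect_equal(bd_closed, bhattacharyya_numeric(g1, g2), tolerance = 1e-3)
  }
})

test_that("ProbIoU matches closed-form cases and vanishing-overlap limits", {
  g <- box_to_gaussian(rotated_box(0.1, 0.2, 0.3, 0.2, 0.5))
  expect_equal(prob_iou(g, g), 1)
  expect_equal(prob_iou(gaussian_box(0, 0, 1 / 12, 1 / 12),
                        gaussian_box(1, 0, 1 / 12, 1 / 12)),
               1 - sqrt(1 - exp(-1.5)), tolerance = 1e-12)
  # separation of 1000 box widths: similarity 0 within 1e-6
  expect_lt(prob_iou(box_to_gaussian(rotated_box(0, 0, 1, 1, 0)),
                     box_to_gaussian(rotated_box(1000, 0, 1, 1, 0))), 1e-6)
  # loss is the complement
  p <- box_to_gaussian(rotated_box(0, 0, 1, 1, 0))
  q <- box_to_gaussian(rotated_box(1, 0, 1, 1, 0))
  expect_equal(prob_iou_loss(p, q), 1 - prob_iou(p, q))
  expect_equal(prob_iou_loss(p, p), 0)
})

test_that("ProbIoU loss is bounded, symmetric, and monotone in separation", {
  set.seed(13)
  for (i in 1:1000) {
    p <- random_box(); q <- random_box()
    l <- prob_iou_loss(p, q)
    expect_gte(l, 0); expect_lte(l, 1)
    expect_equal(l, prob_iou_loss(q, p), tolerance = 1e-12)
  }
  # fixed equal shapes: similarity strictly decreases with center distance
  # (range chosen where exp(-BD) stays above double-precision resolution)
  base <- rotated_box(0, 0, 0.4, 0.2, 0.3)
  d <- seq(0, 1.2, by = 0.1)
  sims <- vapply(d, function(dd) {
    prob_iou(base, rotated_box(dd, 0, 0.4, 0.2, 0.3))
  }, numeric(1))
  expect_true(all(diff(sims) < 0))
})

test_that("ProbIoU ranks overlapping box pairs consistently with skew IOU", {
  set.seed(19)
  n <- 1000
  si <- pi_ <- numeric(n)
  for (i in seq_len(n)) {
    p <- random_box(); q <- random_box()
    si[i] <- skew_iou(p, q)
    pi_[i] <- prob_iou(p, q)
  }
  # skew IOU ties all disjoint pairs at zero while the Gaussian similarity
  # still ranks them by distance, so the rank comparison is made where the
  # geometric IOU discriminates
  ov <- si > 0
  expect_gt(sum(ov), 100)
  expect_gt(cor(si[ov], pi_[ov], method = "spearman"), 0.8)
  # both reach 1 only at identity
  expect_equal(prob_iou(box_to_gaussian(rotated_box(0, 0, 1, 2, 0.2)),
                        box_to_gaussian(rotated_box(0, 0, 1, 2, 0.2))), 1)
  expect_lt(max(pi_[si < 1]), 1)
})

test_that("DFL target splitting and clamping follow the bracketing rule", {
  t <- dfl_target(3.0, 16)
  expect_equal(c(t$yi, t$yi1), c(3L, 4L))
  expect_equal(t$weights, c(1, 0))
  t <- dfl_target(3.5, 16)
  expect_equal(t$weights, c(0.5, 0.5))
  t <- dfl_target(16, 16) # upper clamp
  expect_equal(c(t$yi, t$yi1), c(15L, 16L))
  expect_equal(t$weights, c(0, 1))
  expect_error(dfl_target(-0.1, 16), "outside")
  expect_error(dfl_target(16.01, 16), "outside")
})

test_that("DFL loss matches direct evaluation and clamps empty bins", {
  one_hot <- function(i, reg_max = 16) {
    p <- numeric(reg_max + 1); p[i + 1] <- 1
    bin_distribution(p, reg_max)
  }
  expect_equal(dfl_loss(one_hot(3), dfl_target(3, 16)), 0)
  half <- numeric(17); half[4:5] <- 0.5
  expect_equal(dfl_loss(bin_distribution(half, 16), dfl_target(3.5, 16)),
               log(2), tolerance = 1e-12)
  d <- numeric(17); d[4] <- 0.3; d[5] <- 0.7
  expect_equal(dfl_loss(bin_distribution(d, 16), dfl_target(3.7, 16)),
               -(0.3 * log(0.3) + 0.7 * log(0.7)), tolerance = 1e-12)
  # zero mass on a needed bin: finite thanks to the log clamp
  expect_true(is.finite(dfl_loss(one_hot(0), dfl_target(8.5, 16))))
})

test_that("two-hot linear-weight distribution minimizes DFL and decodes exactly", {
  set.seed(29)
  for (rep in 1:25) {
    y <- runif(1, 0, 16)
    tgt <- dfl_target(y, 16)
    star <- dfl_ideal_distribution(tgt)
    expect_equal(decode_expectation(star), y, tolerance = 1e-12)
    l_star <- dfl_loss(star, tgt)
    for (k in 1:40) { # random competitor distributions
      p <- stats::rexp(17); p <- p / sum(p)
      expect_gte(dfl_loss(bin_distribution(p, 16), tgt), l_star - 1e-12)
    }
  }
})

test_that("expectation decoding matches closed forms", {
  p <- numeric(17); p[6] <- 1
  expect_equal(decode_expectation(bin_distribution(p, 16)), 5)
  p <- numeric(17); p[4:5] <- 0.5
  expect_equal(decode_expectation(bin_distribution(p, 16)), 3.5)
  expect_equal(decode_expectation(bin_distribution(rep(1 / 17, 17), 16)), 8)
})

test_that("total loss combines components with the 0.8/0.2 weighting", {
  expect_equal(total_loss(1, 0)$l_total, 0.8)
  expect_equal(total_loss(0, 0)$l_total, 0)
  expect_equal(total_loss(0.5, 0.5)$l_total, 0.5)
  set.seed(37)
  for (i in 1:50) {
    lp <- runif(1); ld <- rexp(1)
    lb <- total_loss(lp, ld)
    expect_equal(lb$l_total, 0.8 * lp + 0.2 * ld, tolerance = 1e-12)
  }
  expect_error(total_loss(1.2, 0), "0, 1")
  expect_error(total_loss(0.5, -1), ">= 0")
})

test_that("bin distributions validate their invariants", {
  expect_error(bin_distribution(rep(0.1, 5), 16), "length")
  expect_error(bin_distribution(c(rep(0, 16), 0.5), 16), "sum to 1")
  p <- numeric(17); p[1] <- 1.0000005
  expect_silent(bin_distribution(p / sum(p), 16))
})
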