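# Shared fixtures and independent oracles for the test suite.

# random rotated box: center in the unit square, sides in [0.05, 0.5],
# angle in [0, pi)
random_box <- function() {
  rotated_box(runif(1), runif(1), runif(1, 0.05, 0.5), runif(1, 0.05, 0.5),
              runif(1, 0, pi))
}

# closed-form IOU of two axis-aligned boxes via interval overlap
aa_iou <- function(p, q) {
  ox <- max(0, min(p$cx + p$w / 2, q$cx + q$w / 2) -
              max(p$cx - p$w / 2, q$cx - q$w / 2))
  oy <- max(0, min(p$cy + p$h / 2, q$cy + q$h / 2) -
              max(p$cy - p$h / 2, q$cy - q$h / 2))
  inter <- ox * oy
  inter / (p$w * p$h + q$w * q$h - inter)
}

# numeric Bhattacharyya distance between two 2-D Gaussians by tensorized
# Gauss-Legendre quadrature of the Bhattacharyya coefficient integral
# BC = int sqrt(p(x) q(x)) dx; BD = -log(BC)
bhattacharyya_numeric <- function(g1, g2, n_nodes = 120) {
  dens <- function(g, X, Y) {
    det_s <- g$a * g$b - g$c^2
    dx <- X - g$x; dy <- Y - g$y
    qf <- (g$b * dx^2 - 2 * g$c * dx * dy + g$a * dy^2) / det_s
    exp(-qf / 2) / (2 * pi * sqrt(det_s))
  }
  sd_max <- sqrt(max(g1$a, g1$b, g2$a, g2$b))
  xr <- range(g1$x, g2$x) + c(-8, 8) * sd_max
  yr <- range(g1$y, g2$y) + c(-8, 8) * sd_max
  glx <- pracma::gaussLegendre(n_nodes, xr[1], xr[2])
  gly <- pracma::gaussLegendre(n_nodes, yr[1], yr[2])
  X <- outer(glx$x, rep(1, n_nodes))
  Y <- outer(rep(1, n_nodes), gly$x)
  Wt <- outer(glx$w, gly$w)
  bc <- sum(Wt * sqrt(dens(g1, X, Y) * dens(g2, X, Y)))
  -log(bc)
}

# brute-force AP oracle: re-evaluates precision/recall from scratch at every
# confidence cutoff (top-k prefix) with fresh greedy matching, then
# integrates the monotone precision envelope over recall
ap_oracle <- function(dets, truths, thr) {
  n_truth <- length(truths)
  if (n_truth == 0L) return(NA_real_)
  if (!length(dets)) return(0)
  ord <- order(-vapply(dets, function(d) d$confidence, numeric(1)))
  nk <- length(dets)
  prec <- rec <- numeric(nk)
  for (k in seq_len(nk)) {
    top <- dets[ord[seq_len(k)]]
    claimed <- rep(FALSE, n_truth)
    tp <- 0L
    for (d in top) { # already in descending confidence
      best_iou <- -1; best_t <- 0L
      for (ti in seq_len(n_truth)) {
        if (claimed[ti]) next
        iou <- skew_iou(d$box, truths[[ti]])
        if (iou > best_iou + 1e-15) { best_iou <- iou; best_t <- ti }
      }
      if (best_t > 0L && best_iou >= thr) { claimed[best_t] <- TRUE; tp <- tp + 1L }
    }
    prec[k] <- tp / k
    rec[k] <- tp / n_truth
  }
  env <- rev(cummax(rev(prec)))
  sum(env * diff(c(0, rec)))
}

# earth-mover distance between grey histograms of two images, in grey levels
# on the 0-255 scale
histogram_emd <- function(a, b, nbins = 256) {
  brk <- seq(0, 1, length.out = nbins + 1)
  ha <- hist(pmin(pmax(a, 0), 1), breaks = brk, plot = FALSE)$counts
  hb <- hist(pmin(pmax(b, 0), 1), breaks = brk, plot = FALSE)$counts
  ha <- ha / sum(ha); hb <- hb / sum(hb)
  sum(abs(cumsum(ha) - cumsum(hb))) * (255 / nbins)
}

expect_box_equal <- function(a, b, tol = 1e-6) {
  ca <- canonical_box(a); cb <- canonical_box(b)
  expect_lt(abs(ca$cx - cb$cx), tol)
  expect_lt(abs(ca$cy - cb$cy), tol)
  expect_lt(abs(ca$w - cb$w), tol)
  expect_lt(abs(ca$h - cb$h), tol)
  # angle comparison modulo pi
  dth <- abs(normalize_angle(ca$theta - cb$theta))
  expect_lt(min(dth, pi - dth), tol)
}

# box equality in the normalized coordinates of a W x H frame (the precision
# the YOLO-OBB text format guarantees)
expect_obb_equal <- function(a, b, size, tol = 1e-9) {
  ca <- canonical_box(a); cb <- canonical_box(b)
  expect_lt(abs(ca$cx - cb$cx) / size[1], tol)
  expect_lt(abs(ca$cy - cb$cy) / size[2], tol)
  expect_lt(abs(ca$w - cb$w) / size[1], tol)
  expect_lt(abs(ca$h - cb$h) / size[2], tol)
  dth <- abs(normalize_angle(ca$theta - cb$theta))
  expect_lt(min(dth, pi - dth), tol)
}
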