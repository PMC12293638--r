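# ProbIoU: rotated-box similarity through Gaussian surrogates and the
# Bhattacharyya distance. A rectangle is summarized by the mean and covariance
# of the uniform distribution over it; the distance between two such Gaussians
# splits into a center term B1 and a shape term B2, and the similarity is
# 1 - Hellinger distance.

#' Gaussian surrogate of a rotated box
#'
#' Constructs a 2-D Gaussian `(x, y, a, b, c)` where `(x, y)` is the mean and
#' `[[a, c], [c, b]]` the covariance (a = xx entry, b = yy entry, c = xy
#' entry). The covariance must be positive-definite.
#'
#' @param x,y Mean.
#' @param a,b,c Covariance entries; requires `a > 0`, `b > 0`, `a*b - c^2 > 0`.
#' @return An object of class `gaussian_box`.
#' @export
gaussian_box <- function(x, y, a, b, c = 0) {
  stopifnot(is.numeric(x), is.numeric(y), is.numeric(a), is.numeric(b),
            is.numeric(c), all(is.finite(c(x, y, a, b, c))))
  if (a <= 0 || b <= 0 || a * b - c^2 <= 0) {
    stop("covariance (a, b, c) must be positive-definite: a > 0, b > 0, a*b - c^2 > 0")
  }
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 a = as.numeric(a), b = as.numeric(b), c = as.numeric(c)),
            class = "gaussian_box")
}

#' @export
print.gaussian_box <- function(x, ...) {
  cat(sprintf("<gaussian_box> mean (%.4g, %.4g)  cov [a=%.4g, b=%.4g, c=%.4g]\n",
              x$x, x$y, x$a, x$b, x$c))
  invisible(x)
}

#' Map a rotated box to its Gaussian surrogate
#'
#' Uses the covariance of the uniform distribution over the rectangle:
#' `R(theta) diag(w^2/12, h^2/12) R(theta)'`, with the box center as mean.
#' This is the established surrogate for Gaussian rotated-box losses.
#'
#' @param box A [rotated_box()].
#' @return A [gaussian_box()].
#' @examples
#' box_to_gaussian(rotated_box(0, 0, 2, 1, 0)) # a = 1/3, b = 1/12, c = 0
#' @export
box_to_gaussian <- function(box) {
  stopifnot(is_rotated_box(box))
  ct <- cos(box$theta); st <- sin(box$theta)
  vw <- box$w^2 / 12; vh <- box$h^2 / 12
  gaussian_box(
    box$cx, box$cy,
    a = vw * ct^2 + vh * st^2,
    b = vw * st^2 + vh * ct^2,
    c = (vw - vh) * ct * st
  )
}

as_gaussian <- function(x) {
  if (inherits(x, "gaussian_box")) return(x)
  if (is_rotated_box(x)) return(box_to_gaussian(x))
  stop("expected a gaussian_box or rotated_box")
}

#' Bhattacharyya terms between two Gaussian boxes
#'
#' Computes the closed-form Bhattacharyya distance between two 2-D Gaussians,
#' split into the center term
#' \deqn{B_1 = \frac{1}{4}\,\frac{(a_1+a_2)(y_1-y_2)^2 + (b_1+b_2)(x_1-x_2)^2 +
#'   2(c_1+c_2)(x_2-x_1)(y_1-y_2)}{(a_1+a_2)(b_1+b_2) - (c_1+c_2)^2}}
#' and the shape term
#' \deqn{B_2 = \frac{1}{2}\ln\frac{(a_1+a_2)(b_1+b_2) - (c_1+c_2)^2}
#'   {4\sqrt{(a_1 b_1 - c_1^2)(a_2 b_2 - c_2^2)}}.}
#' Both are nonnegative and their sum `BD = B1 + B2` vanishes iff the two
#' Gaussians coincide.
#'
#' @param p,q [gaussian_box()] objects (or [rotated_box()]es, converted via
#'   [box_to_gaussian()]).
#' @return A list with components `B1`, `B2` and `BD = B1 + B2`.
#' @export
bhattacharyya_terms <- function(p, q) {
  p <- as_gaussian(p); q <- as_gaussian(q)
  As <- p$a + q$a; Bs <- p$b + q$b; Cs <- p$c + q$c
  det_s <- As * Bs - Cs^2
  dx <- p$x - q$x; dy <- p$y - q$y
  B1 <- 0.25 * (As * dy^2 + Bs * dx^2 + 2 * Cs * (-dx) * dy) / det_s
  det1 <- p$a * p$b - p$c^2
  det2 <- q$a * q$b - q$c^2
  B2 <- 0.5 * log(det_s / (4 * sqrt(det1 * det2)))
  # guard tiny negative rounding on identical inputs
  list(B1 = max(B1, 0), B2 = max(B2, 0), BD = max(B1, 0) + max(B2, 0))
}

#' ProbIoU similarity between two boxes
#'
#' The Bhattacharyya distance `BD = B1 + B2` gives the Bhattacharyya
#' coefficient `exp(-BD)`, hence the Hellinger distance
#' `H = sqrt(1 - exp(-BD))`; the similarity is `1 - H`, which lies in
#' `[0, 1]` and equals 1 iff the two Gaussians are identical.
#'
#' @param p,q [gaussian_box()] or [rotated_box()] objects.
#' @return Similarity in `[0, 1]`; symmetric.
#' @export
prob_iou <- function(p, q) {
  bd <- bhattacharyya_terms(p, q)$BD
  1 - sqrt(max(0, min(1, 1 - exp(-bd))))
}

#' ProbIoU regression loss
#'
#' `1 - prob_iou(p, q)`, bounded in `[0, 1]`: 0 for identical boxes, tending
#' to 1 as the Gaussians separate.
#'
#' @inheritParams prob_iou
#' @return Loss in `[0, 1]`.
#' @export
prob_iou_loss <- function(p, q) {
  1 - prob_iou(p, q)
}
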