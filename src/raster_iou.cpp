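#include <Rcpp.h>
#include <cmath>

// Grid-sampling IOU between two rotated boxes, independent of the polygon
// triangulation path: an n x n lattice of cell centers is laid over the joint
// axis-aligned bounding box of the two rectangles and membership is counted
// per rectangle via its local frame |R(-theta) (p - c)| <= (w/2, h/2).

static inline void half_extent(double w, double h, double c, double s,
                               double &ex, double &ey) {
  ex = 0.5 * (std::fabs(w * c) + std::fabs(h * s));
  ey = 0.5 * (std::fabs(w * s) + std::fabs(h * c));
}

// [[Rcpp::export]]
double raster_iou_cpp(Rcpp::NumericVector p, Rcpp::NumericVector q, int n) {
  if (p.size() != 5 || q.size() != 5)
    Rcpp::stop("boxes must be numeric vectors (cx, cy, w, h, theta)");
  if (n < 2) Rcpp::stop("grid size must be >= 2");

  const double cp = std::cos(p[4]), sp = std::sin(p[4]);
  const double cq = std::cos(q[4]), sq = std::sin(q[4]);
  const double phw = p[2] / 2.0, phh = p[3] / 2.0;
  const double qhw = q[2] / 2.0, qhh = q[3] / 2.0;

  double pex, pey, qex, qey;
  half_extent(p[2], p[3], cp, sp, pex, pey);
  half_extent(q[2], q[3], cq, sq, qex, qey);

  const double x0 = std::min(p[0] - pex, q[0] - qex);
  const double x1 = std::max(p[0] + pex, q[0] + qex);
  const double y0 = std::min(p[1] - pey, q[1] - qey);
  const double y1 = std::max(p[1] + pey, q[1] + qey);

  const double dx = (x1 - x0) / n;
  const double dy = (y1 - y0) / n;

  long long cp_n = 0, cq_n = 0, ci_n = 0;
  for (int iy = 0; iy < n; ++iy) {
    const double y = y0 + (iy + 0.5) * dy;
    const double pyd = y - p[1];
    const double qyd = y - q[1];
    for (int ix = 0; ix < n; ++ix) {
      const double x = x0 + (ix + 0.5) * dx;
      const double pxd = x - p[0];
      const double qxd = x - q[0];
      const bool in_p = std::fabs(pxd * cp + pyd * sp) <= phw &&
                        std::fabs(-pxd * sp + pyd * cp) <= phh;
      const bool in_q = std::fabs(qxd * cq + qyd * sq) <= qhw &&
                        std::fabs(-qxd * sq + qyd * cq) <= qhh;
      cp_n += in_p;
      cq_n += in_q;
      ci_n += (in_p && in_q);
    }
  }
  const long long un = cp_n + cq_n - ci_n;
  if (un <= 0) return 0.0;
  return static_cast<double>(ci_n) / static_cast<double>(un);
}
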