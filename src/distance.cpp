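// Nearest point-to-triangle-soup distances (unsigned).
// Closest-point-on-triangle after Ericson, "Real-Time Collision Detection".
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// squared distance from point p to triangle (a,b,c)
static double pointTriDist2(const double *p, const double *a, const double *b,
                            const double *c) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  double q[3];
  if (d1 <= 0.0 && d2 <= 0.0) {
    q[0] = a[0]; q[1] = a[1]; q[2] = a[2];
  } else {
    double bp[3], cp[3];
    for (int i = 0; i < 3; ++i) { bp[i] = p[i] - b[i]; cp[i] = p[i] - c[i]; }
    double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
    double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
    if (d3 >= 0.0 && d4 <= d3) {
      q[0] = b[0]; q[1] = b[1]; q[2] = b[2];
    } else if (d6 >= 0.0 && d5 <= d6) {
      q[0] = c[0]; q[1] = c[1]; q[2] = c[2];
    } else {
      double vc = d1 * d4 - d3 * d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = (d1 - d3) != 0.0 ? clamp01(d1 / (d1 - d3)) : 0.0;
        for (int i = 0; i < 3; ++i) q[i] = a[i] + v * ab[i];
      } else {
        double vb = d5 * d2 - d1 * d6;
        if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
          double w = (d2 - d6) != 0.0 ? clamp01(d2 / (d2 - d6)) : 0.0;
          for (int i = 0; i < 3; ++i) q[i] = a[i] + w * ac[i];
        } else {
          double va = d3 * d6 - d5 * d4;
          if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
            double denom = (d4 - d3) + (d5 - d6);
            double w = denom != 0.0 ? clamp01((d4 - d3) / denom) : 0.0;
            for (int i = 0; i < 3; ++i) q[i] = b[i] + w * (c[i] - b[i]);
          } else {
            double denom = va + vb + vc;
            double v = denom != 0.0 ? vb / denom : 1.0 / 3.0;
            double w = denom != 0.0 ? vc / denom : 1.0 / 3.0;
            for (int i = 0; i < 3; ++i) q[i] = a[i] + v * ab[i] + w * ac[i];
          }
        }
      }
    }
  }
  double dx = p[0] - q[0], dy = p[1] - q[1], dz = p[2] - q[2];
  return dx * dx + dy * dy + dz * dz;
}

//' @noRd
// [[Rcpp::export(name = ".cppNearestSurfaceDistance")]]
NumericVector cppNearestSurfaceDistance(NumericMatrix pts, NumericMatrix V,
                                        IntegerMatrix F) {
  const int np = pts.nrow(), nf = F.nrow();
  NumericVector out(np);
  // per-face corner coords and bounding boxes, plus centroids for seeding
  std::vector<double> tri(9 * nf), lo(3 * nf), hi(3 * nf), cen(3 * nf);
  for (int f = 0; f < nf; ++f) {
    for (int k = 0; k < 3; ++k) {
      int v = F(f, k) - 1;
      for (int i = 0; i < 3; ++i) tri[9 * f + 3 * k + i] = V(v, i);
    }
    for (int i = 0; i < 3; ++i) {
      double a = tri[9 * f + i], b = tri[9 * f + 3 + i], c = tri[9 * f + 6 + i];
      lo[3 * f + i] = std::min(a, std::min(b, c));
      hi[3 * f + i] = std::max(a, std::max(b, c));
      cen[3 * f + i] = (a + b + c) / 3.0;
    }
  }
  for (int pI = 0; pI < np; ++pI) {
    double p[3] = { pts(pI, 0), pts(pI, 1), pts(pI, 2) };
    // seed with the face of nearest centroid
    int seed = 0;
    double bestc = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      double d2 = 0.0;
      for (int i = 0; i < 3; ++i) {
        double d = p[i] - cen[3 * f + i];
        d2 += d * d;
      }
      if (d2 < bestc) { bestc = d2; seed = f; }
    }
    double best = pointTriDist2(p, &tri[9 * seed], &tri[9 * seed + 3],
                                &tri[9 * seed + 6]);
    for (int f = 0; f < nf; ++f) {
      // bbox rejection
      double d2 = 0.0;
      for (int i = 0; i < 3; ++i) {
        double d = 0.0;
        if (p[i] < lo[3 * f + i]) d = lo[3 * f + i] - p[i];
        else if (p[i] > hi[3 * f + i]) d = p[i] - hi[3 * f + i];
        d2 += d * d;
      }
      if (d2 >= best) continue;
      double dd = pointTriDist2(p, &tri[9 * f], &tri[9 * f + 3], &tri[9 * f + 6]);
      if (dd < best) best = dd;
    }
    out[pI] = std::sqrt(best);
  }
  return out;
}
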