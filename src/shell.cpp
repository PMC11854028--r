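// Shell element kernels: St. Venant-Kirchhoff membrane triangles (plane
// stress) plus hinge-based bending on interior/ghost edges. Energies and
// analytic gradients; element Hessians by central finite differences of the
// analytic gradient (symmetrised on assembly).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::vec;
using arma::mat;

static inline void cross3(const double *a, const double *b, double *c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double norm3(const double *a) { return std::sqrt(dot3(a, a)); }

// ---- membrane --------------------------------------------------------------

struct MembranePre {
  double Dminv[4]; // column-major 2x2
  double A0;
};

// energy + gradient wrt the 9 coords (x0,x1,x2 stacked xyz)
static double membraneEG(const double *x0, const double *x1, const double *x2,
                         const MembranePre &pre, double mu, double lam,
                         double h, double *grad) {
  double d1[3], d2[3];
  for (int i = 0; i < 3; ++i) { d1[i] = x1[i] - x0[i]; d2[i] = x2[i] - x0[i]; }
  // F = Ds * Dminv, Ds = [d1 d2] (3x2)
  double F0[3], F1[3]; // columns of F
  for (int i = 0; i < 3; ++i) {
    F0[i] = d1[i] * pre.Dminv[0] + d2[i] * pre.Dminv[1];
    F1[i] = d1[i] * pre.Dminv[2] + d2[i] * pre.Dminv[3];
  }
  double E00 = 0.5 * (dot3(F0, F0) - 1.0);
  double E11 = 0.5 * (dot3(F1, F1) - 1.0);
  double E01 = 0.5 * dot3(F0, F1);
  double trE = E00 + E11;
  double psi = mu * (E00 * E00 + E11 * E11 + 2.0 * E01 * E01) +
               0.5 * lam * trE * trE;
  double W = h * pre.A0 * psi;
  if (grad) {
    // S = 2 mu E + lam tr(E) I  (2nd PK, 2x2)
    double S00 = 2.0 * mu * E00 + lam * trE;
    double S11 = 2.0 * mu * E11 + lam * trE;
    double S01 = 2.0 * mu * E01;
    // dW/dF = h A0 F S ; dW/dDs = dW/dF Dminv^T
    double P0[3], P1[3];
    for (int i = 0; i < 3; ++i) {
      P0[i] = h * pre.A0 * (F0[i] * S00 + F1[i] * S01);
      P1[i] = h * pre.A0 * (F0[i] * S01 + F1[i] * S11);
    }
    double G1[3], G2[3];
    for (int i = 0; i < 3; ++i) {
      G1[i] = P0[i] * pre.Dminv[0] + P1[i] * pre.Dminv[2];
      G2[i] = P0[i] * pre.Dminv[1] + P1[i] * pre.Dminv[3];
    }
    for (int i = 0; i < 3; ++i) {
      grad[i] = -(G1[i] + G2[i]);
      grad[3 + i] = G1[i];
      grad[6 + i] = G2[i];
    }
  }
  return W;
}

// ---- hinge bending ---------------------------------------------------------

// signed dihedral angle for hinge (p0 | p1-p2 edge | p3); 0 when flat
static double dihedral(const double *p0, const double *p1, const double *p2,
                       const double *p3) {
  double e[3], a[3], b[3], n1[3], n2[3];
  for (int i = 0; i < 3; ++i) {
    e[i] = p2[i] - p1[i];
    a[i] = p0[i] - p1[i];
    b[i] = p3[i] - p2[i];
  }
  cross3(e, a, n1); // normal of tri (p1,p2,p0)
  double me[3];
  for (int i = 0; i < 3; ++i) me[i] = -e[i];
  cross3(me, b, n2); // normal of tri (p2,p1,p3)
  double ne1 = norm3(n1), ne2 = norm3(n2), le = norm3(e);
  if (ne1 <= 0.0 || ne2 <= 0.0 || le <= 0.0) return 0.0;
  double cx[3];
  cross3(n1, n2, cx);
  double s = dot3(cx, e) / (ne1 * ne2 * le);
  double c = dot3(n1, n2) / (ne1 * ne2);
  return std::atan2(s, c);
}

// gradient of the dihedral angle wrt the 12 coords
static void dihedralGrad(const double *p0, const double *p1, const double *p2,
                         const double *p3, double *g) {
  double e[3], a[3], b[3], n1[3], n2[3];
  for (int i = 0; i < 3; ++i) {
    e[i] = p2[i] - p1[i];
    a[i] = p0[i] - p1[i];
    b[i] = p3[i] - p2[i];
  }
  cross3(e, a, n1);
  double me[3];
  for (int i = 0; i < 3; ++i) me[i] = -e[i];
  cross3(me, b, n2);
  double n1sq = dot3(n1, n1), n2sq = dot3(n2, n2), le = norm3(e);
  double inv1 = le / n1sq, inv2 = le / n2sq;
  double c01 = dot3(a, e) / (le * le);        // projection of p0 on edge
  double c31 = dot3(b, e) / (le * le) + 1.0;  // p3 relative to p1 along edge
  // d theta / d p0 = le * n1 / |n1|^2 ; d theta / d p3 = le * n2 / |n2|^2
  for (int i = 0; i < 3; ++i) {
    g[0 + i] = -inv1 * n1[i];
    g[9 + i] = -inv2 * n2[i];
    g[3 + i] = -(c01 - 1.0) * inv1 * n1[i] - (c31 - 1.0) * inv2 * n2[i];
    g[6 + i] = c01 * inv1 * n1[i] + c31 * inv2 * n2[i];
  }
}

static double hingeEG(const double *p0, const double *p1, const double *p2,
                      const double *p3, double k, double theta0, double *grad) {
  double th = dihedral(p0, p1, p2, p3);
  double d = th - theta0;
  if (grad) {
    double gt[12];
    dihedralGrad(p0, p1, p2, p3, gt);
    for (int i = 0; i < 12; ++i) grad[i] = 2.0 * k * d * gt[i];
  }
  return k * d * d;
}

//' @noRd
// [[Rcpp::export(name = ".cppDihedralAngles")]]
NumericVector cppDihedralAngles(NumericMatrix X, IntegerMatrix H) {
  int nh = H.nrow();
  NumericVector out(nh);
  std::vector<double> P(X.nrow() * 3);
  for (int v = 0; v < X.nrow(); ++v)
    for (int i = 0; i < 3; ++i) P[3 * v + i] = X(v, i);
  for (int hI = 0; hI < nh; ++hI) {
    const double *p0 = &P[3 * (H(hI, 0) - 1)];
    const double *p1 = &P[3 * (H(hI, 1) - 1)];
    const double *p2 = &P[3 * (H(hI, 2) - 1)];
    const double *p3 = &P[3 * (H(hI, 3) - 1)];
    out[hI] = dihedral(p0, p1, p2, p3);
  }
  return out;
}

// Assemble elastic energy, per-group gradient, and (optionally) the tangent
// stiffness with per-group scaling factors applied.
//' @noRd
// [[Rcpp::export(name = ".cppShellAssemble")]]
List cppShellAssemble(NumericMatrix X, NumericMatrix X0, IntegerMatrix F,
                      NumericVector faceMu, NumericVector faceLam,
                      double thickness, IntegerMatrix H, NumericVector hingeK,
                      NumericVector hingeTheta0, IntegerVector faceGroup,
                      IntegerVector hingeGroup, int nGroups,
                      NumericVector groupScale, bool wantHessian) {
  const int n = X.nrow(), m = F.nrow(), nh = H.nrow();
  std::vector<double> P(3 * n), P0(3 * n);
  for (int v = 0; v < n; ++v)
    for (int i = 0; i < 3; ++i) {
      P[3 * v + i] = X(v, i);
      P0[3 * v + i] = X0(v, i);
    }
  mat grad(3 * n, nGroups, arma::fill::zeros);
  vec energy(nGroups, arma::fill::zeros);

  std::size_t nnz = wantHessian ? (std::size_t)m * 81 + (std::size_t)nh * 144 : 0;
  arma::umat locs;
  arma::vec vals;
  if (wantHessian) {
    locs.set_size(2, nnz);
    vals.set_size(nnz);
  }
  std::size_t ptr = 0;
  const double eps = 1e-5;

  // membrane
  for (int f = 0; f < m; ++f) {
    int vi[3] = { F(f, 0) - 1, F(f, 1) - 1, F(f, 2) - 1 };
    const double *r0 = &P0[3 * vi[0]], *r1 = &P0[3 * vi[1]], *r2 = &P0[3 * vi[2]];
    // rest-state local frame
    double u1[3], u2[3];
    for (int i = 0; i < 3; ++i) { u1[i] = r1[i] - r0[i]; u2[i] = r2[i] - r0[i]; }
    double l1 = norm3(u1);
    if (l1 <= 0.0) stop("degenerate rest triangle");
    double e1[3];
    for (int i = 0; i < 3; ++i) e1[i] = u1[i] / l1;
    double p = dot3(u2, e1);
    double e2[3];
    for (int i = 0; i < 3; ++i) e2[i] = u2[i] - p * e1[i];
    double l2 = norm3(e2);
    if (l2 <= 0.0) stop("degenerate rest triangle");
    for (int i = 0; i < 3; ++i) e2[i] /= l2;
    // Dm = [[l1, p], [0, q]] with q = u2.e2
    double q = dot3(u2, e2);
    double det = l1 * q;
    MembranePre pre;
    pre.A0 = 0.5 * det;
    // inverse, column-major
    pre.Dminv[0] = q / det;
    pre.Dminv[1] = 0.0;
    pre.Dminv[2] = -p / det;
    pre.Dminv[3] = l1 / det;

    double xe[9];
    for (int k = 0; k < 3; ++k)
      for (int i = 0; i < 3; ++i) xe[3 * k + i] = P[3 * vi[k] + i];
    double ge[9];
    double W = membraneEG(&xe[0], &xe[3], &xe[6], pre, faceMu[f], faceLam[f],
                          thickness, ge);
    int g = faceGroup[f] - 1;
    energy[g] += W;
    for (int k = 0; k < 3; ++k)
      for (int i = 0; i < 3; ++i) grad(3 * vi[k] + i, g) += ge[3 * k + i];
    if (wantHessian) {
      double Hd[81];
      double gp[9], gm[9], xw[9];
      for (int c = 0; c < 9; ++c) {
        std::memcpy(xw, xe, sizeof(xw));
        xw[c] = xe[c] + eps;
        membraneEG(&xw[0], &xw[3], &xw[6], pre, faceMu[f], faceLam[f], thickness, gp);
        xw[c] = xe[c] - eps;
        membraneEG(&xw[0], &xw[3], &xw[6], pre, faceMu[f], faceLam[f], thickness, gm);
        for (int r = 0; r < 9; ++r) Hd[9 * c + r] = (gp[r] - gm[r]) / (2.0 * eps);
      }
      double s = groupScale[g];
      for (int c = 0; c < 9; ++c)
        for (int r = 0; r < 9; ++r) {
          locs(0, ptr) = 3 * vi[r / 3] + (r % 3);
          locs(1, ptr) = 3 * vi[c / 3] + (c % 3);
          vals(ptr) = 0.5 * s * (Hd[9 * c + r] + Hd[9 * r + c]);
          ++ptr;
        }
    }
  }

  // hinges
  for (int hI = 0; hI < nh; ++hI) {
    int vi[4] = { H(hI, 0) - 1, H(hI, 1) - 1, H(hI, 2) - 1, H(hI, 3) - 1 };
    double xe[12];
    for (int k = 0; k < 4; ++k)
      for (int i = 0; i < 3; ++i) xe[3 * k + i] = P[3 * vi[k] + i];
    double ge[12];
    double W = hingeEG(&xe[0], &xe[3], &xe[6], &xe[9], hingeK[hI],
                       hingeTheta0[hI], ge);
    int g = hingeGroup[hI] - 1;
    energy[g] += W;
    for (int k = 0; k < 4; ++k)
      for (int i = 0; i < 3; ++i) grad(3 * vi[k] + i, g) += ge[3 * k + i];
    if (wantHessian) {
      double Hd[144];
      double gp[12], gm[12], xw[12];
      for (int c = 0; c < 12; ++c) {
        std::memcpy(xw, xe, sizeof(xw));
        xw[c] = xe[c] + eps;
        hingeEG(&xw[0], &xw[3], &xw[6], &xw[9], hingeK[hI], hingeTheta0[hI], gp);
        xw[c] = xe[c] - eps;
        hingeEG(&xw[0], &xw[3], &xw[6], &xw[9], hingeK[hI], hingeTheta0[hI], gm);
        for (int r = 0; r < 12; ++r) Hd[12 * c + r] = (gp[r] - gm[r]) / (2.0 * eps);
      }
      double s = groupScale[g];
      for (int c = 0; c < 12; ++c)
        for (int r = 0; r < 12; ++r) {
          locs(0, ptr) = 3 * vi[r / 3] + (r % 3);
          locs(1, ptr) = 3 * vi[c / 3] + (c % 3);
          vals(ptr) = 0.5 * s * (Hd[12 * c + r] + Hd[12 * r + c]);
          ++ptr;
        }
    }
  }

  List out = List::create(_["energy"] = wrap(energy), _["grad"] = wrap(grad));
  if (wantHessian) {
    arma::sp_mat K(true, locs, vals, 3 * n, 3 * n); // batch insert, sums dups
    out["K"] = wrap(K);
  }
  return out;
}
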