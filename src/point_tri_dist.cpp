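#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Squared distance from point P to triangle (A, B, C), Eberly's region
// decomposition. All inputs are length-3 arrays in the same (voxel) units.
static double pointTriDist2(const double *P, const double *A,
                            const double *B, const double *C) {
  double E0[3], E1[3], D[3];
  for (int i = 0; i < 3; ++i) {
    E0[i] = B[i] - A[i];
    E1[i] = C[i] - A[i];
    D[i]  = A[i] - P[i];
  }
  double a = E0[0]*E0[0] + E0[1]*E0[1] + E0[2]*E0[2];
  double b = E0[0]*E1[0] + E0[1]*E1[1] + E0[2]*E1[2];
  double c = E1[0]*E1[0] + E1[1]*E1[1] + E1[2]*E1[2];
  double d = E0[0]*D[0]  + E0[1]*D[1]  + E0[2]*D[2];
  double e = E1[0]*D[0]  + E1[1]*D[1]  + E1[2]*D[2];
  double f = D[0]*D[0]   + D[1]*D[1]   + D[2]*D[2];

  double det = a*c - b*b, s = b*e - c*d, t = b*d - a*e;

  if (s + t <= det) {
    if (s < 0.0) {
      if (t < 0.0) { // region 4
        if (d < 0.0) { t = 0.0; s = (-d >= a ? 1.0 : -d/a); }
        else { s = 0.0; t = (e >= 0.0 ? 0.0 : (-e >= c ? 1.0 : -e/c)); }
      } else {       // region 3
        s = 0.0; t = (e >= 0.0 ? 0.0 : (-e >= c ? 1.0 : -e/c));
      }
    } else if (t < 0.0) { // region 5
      t = 0.0; s = (d >= 0.0 ? 0.0 : (-d >= a ? 1.0 : -d/a));
    } else {              // region 0
      double inv = 1.0/det; s *= inv; t *= inv;
    }
  } else {
    if (s < 0.0) { // region 2
      double tmp0 = b + d, tmp1 = c + e;
      if (tmp1 > tmp0) {
        double numer = tmp1 - tmp0, denom = a - 2.0*b + c;
        s = (numer >= denom ? 1.0 : numer/denom); t = 1.0 - s;
      } else {
        s = 0.0; t = (tmp1 <= 0.0 ? 1.0 : (e >= 0.0 ? 0.0 : -e/c));
      }
    } else if (t < 0.0) { // region 6
      double tmp0 = b + e, tmp1 = a + d;
      if (tmp1 > tmp0) {
        double numer = tmp1 - tmp0, denom = a - 2.0*b + c;
        t = (numer >= denom ? 1.0 : numer/denom); s = 1.0 - t;
      } else {
        t = 0.0; s = (tmp1 <= 0.0 ? 1.0 : (d >= 0.0 ? 0.0 : -d/a));
      }
    } else { // region 1
      double numer = (c + e) - (b + d);
      if (numer <= 0.0) { s = 0.0; }
      else {
        double denom = a - 2.0*b + c;
        s = (numer >= denom ? 1.0 : numer/denom);
      }
      t = 1.0 - s;
    }
  }
  double Q[3];
  for (int i = 0; i < 3; ++i) Q[i] = A[i] + s*E0[i] + t*E1[i] - P[i];
  return Q[0]*Q[0] + Q[1]*Q[1] + Q[2]*Q[2];
}

// Shortest distance from each point to the triangulated height field
// h(u, s) (two triangles per grid cell). Cells whose lateral bounding
// rectangle lies farther from the point than the current best distance
// are skipped, which keeps the scan near-linear for thin slabs.
//
// P:  n x 3 matrix (x ~ u axis, y ~ s axis, z ~ height axis), voxel units
// u:  grid coordinates along the first lateral axis (length nu, increasing)
// s:  grid coordinates along the second lateral axis (length ns, increasing)
// H:  nu x ns height matrix (voxel units)
// [[Rcpp::export]]
NumericVector cpp_grid_surface_dist(NumericMatrix P, NumericVector u,
                                    NumericVector s, NumericMatrix H) {
  const int n = P.nrow(), nu = u.size(), ns = s.size();
  if (H.nrow() != nu || H.ncol() != ns)
    stop("height matrix dimensions do not match grid vectors");
  if (nu < 2 || ns < 2)
    stop("surface grid must be at least 2 x 2");
  NumericVector out(n);

  for (int p = 0; p < n; ++p) {
    double px = P(p, 0), py = P(p, 1), pz = P(p, 2);
    double pt[3] = {px, py, pz};

    // initial bound: distance to the vertex nearest laterally
    int iu = 0, is = 0;
    while (iu < nu - 1 && u[iu + 1] < px) ++iu;
    if (iu < nu - 1 && std::fabs(u[iu + 1] - px) < std::fabs(u[iu] - px)) ++iu;
    while (is < ns - 1 && s[is + 1] < py) ++is;
    if (is < ns - 1 && std::fabs(s[is + 1] - py) < std::fabs(s[is] - py)) ++is;
    double dx0 = u[iu] - px, dy0 = s[is] - py, dz0 = H(iu, is) - pz;
    double best2 = dx0*dx0 + dy0*dy0 + dz0*dz0;

    for (int j = 0; j < ns - 1; ++j) {
      double dy = 0.0;
      if (s[j] - py > 0) dy = s[j] - py;
      else if (py - s[j + 1] > 0) dy = py - s[j + 1];
      double dy2 = dy*dy;
      if (dy2 >= best2) continue;
      for (int i = 0; i < nu - 1; ++i) {
        double dx = 0.0;
        if (u[i] - px > 0) dx = u[i] - px;
        else if (px - u[i + 1] > 0) dx = px - u[i + 1];
        if (dx*dx + dy2 >= best2) continue;
        double V00[3] = {u[i],     s[j],     H(i,     j)};
        double V10[3] = {u[i + 1], s[j],     H(i + 1, j)};
        double V01[3] = {u[i],     s[j + 1], H(i,     j + 1)};
        double V11[3] = {u[i + 1], s[j + 1], H(i + 1, j + 1)};
        double d2 = pointTriDist2(pt, V00, V10, V11);
        if (d2 < best2) best2 = d2;
        d2 = pointTriDist2(pt, V00, V11, V01);
        if (d2 < best2) best2 = d2;
      }
    }
    out[p] = std::sqrt(best2);
  }
  return out;
}
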