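#include <Rcpp.h>
#include "geometry.h"

using namespace Rcpp;

// Bead-chain geometry: angles over consecutive triplets, four-quadrant
// dihedrals over consecutive quadruplets, and their Cartesian gradients.
// All gradients are returned in radians/nm; degree conversion happens in
// the energy layer so that the Gaussian restraints (parameterised in
// degrees) stay consistent with the printed -180..180 degree convention.

namespace cg {

double angleRad(const Vec3 &ri, const Vec3 &rj, const Vec3 &rk) {
  Vec3 a = sub(ri, rj), b = sub(rk, rj);
  double na = norm(a), nb = norm(b);
  if (na <= 0.0 || nb <= 0.0)
    Rcpp::stop("degenerate geometry: coincident points in angle triplet");
  double u = dot(a, b) / (na * nb);
  if (u > 1.0) u = 1.0;
  if (u < -1.0) u = -1.0;
  return std::acos(u);
}

// dtheta/dr for the three beads, radians/nm.  1e-12 guard on 1-u^2 keeps
// the arccos derivative finite at collinear geometry.
void angleGrad(const Vec3 &ri, const Vec3 &rj, const Vec3 &rk,
               Vec3 &gi, Vec3 &gj, Vec3 &gk) {
  Vec3 a = sub(ri, rj), b = sub(rk, rj);
  double na = norm(a), nb = norm(b);
  double u = dot(a, b) / (na * nb);
  if (u > 1.0) u = 1.0;
  if (u < -1.0) u = -1.0;
  double s = std::sqrt(std::max(1.0 - u * u, 1e-12));
  double inv = -1.0 / s;
  for (int d = 0; d < 3; ++d) {
    double dui = b.v[d] / (na * nb) - u * a.v[d] / (na * na);
    double duk = a.v[d] / (na * nb) - u * b.v[d] / (nb * nb);
    gi.v[d] = inv * dui;
    gk.v[d] = inv * duk;
    gj.v[d] = -(gi.v[d] + gk.v[d]);
  }
}

// Dihedral with the polymer convention: b1 = j-i, b2 = k-j, b3 = l-k,
// m = b1 x b2, n = b2 x b3, phi = atan2((m x n).b2hat, m.n).
// Planar cis -> 0, planar trans -> 180; mirroring negates phi.
double dihedralRad(const Vec3 &ri, const Vec3 &rj, const Vec3 &rk,
                   const Vec3 &rl) {
  Vec3 b1 = sub(rj, ri), b2 = sub(rk, rj), b3 = sub(rl, rk);
  Vec3 m = cross(b1, b2), n = cross(b2, b3);
  double nm = norm(m), nn = norm(n), nb2 = norm(b2);
  if (nb2 <= 0.0)
    Rcpp::stop("degenerate geometry: coincident central beads in dihedral");
  if (nm <= 1e-12 || nn <= 1e-12)
    Rcpp::stop("degenerate geometry: collinear beads leave dihedral plane undefined");
  double x = dot(m, n);
  double y = dot(cross(m, n), b2) / nb2;
  return std::atan2(y, x);
}

// dphi/dr for the four beads, radians/nm (van Schaik-style closed form).
void dihedralGrad(const Vec3 &ri, const Vec3 &rj, const Vec3 &rk,
                  const Vec3 &rl, Vec3 &gi, Vec3 &gj, Vec3 &gk, Vec3 &gl) {
  Vec3 b1 = sub(rj, ri), b2 = sub(rk, rj), b3 = sub(rl, rk);
  Vec3 m = cross(b1, b2), n = cross(b2, b3);
  double m2 = dot(m, m), n2 = dot(n, n), nb2 = norm(b2);
  double p = dot(b1, b2) / (nb2 * nb2);
  double q = dot(b3, b2) / (nb2 * nb2);
  for (int d = 0; d < 3; ++d) {
    gi.v[d] = -nb2 / m2 * m.v[d];
    gl.v[d] = nb2 / n2 * n.v[d];
    gj.v[d] = -(1.0 + p) * gi.v[d] + q * gl.v[d];
    gk.v[d] = p * gi.v[d] - (1.0 + q) * gl.v[d];
  }
}

} // namespace cg

// [[Rcpp::export(name = ".angleCpp")]]
double angleCpp(NumericVector ri, NumericVector rj, NumericVector rk) {
  return cg::angleRad(cg::asVec(ri), cg::asVec(rj), cg::asVec(rk)) * cg::kRad2Deg;
}

// [[Rcpp::export(name = ".dihedralCpp")]]
double dihedralCpp(NumericVector ri, NumericVector rj, NumericVector rk,
                   NumericVector rl) {
  return cg::dihedralRad(cg::asVec(ri), cg::asVec(rj), cg::asVec(rk),
                         cg::asVec(rl)) * cg::kRad2Deg;
}

// [[Rcpp::export(name = ".angleGradCpp")]]
NumericMatrix angleGradCpp(NumericVector ri, NumericVector rj,
                           NumericVector rk) {
  cg::Vec3 gi, gj, gk;
  cg::angleGrad(cg::asVec(ri), cg::asVec(rj), cg::asVec(rk), gi, gj, gk);
  NumericMatrix out(3, 3);
  for (int d = 0; d < 3; ++d) {
    out(0, d) = gi.v[d]; out(1, d) = gj.v[d]; out(2, d) = gk.v[d];
  }
  return out;
}

// [[Rcpp::export(name = ".dihedralGradCpp")]]
NumericMatrix dihedralGradCpp(NumericVector ri, NumericVector rj,
                              NumericVector rk, NumericVector rl) {
  cg::Vec3 gi, gj, gk, gl;
  cg::dihedralGrad(cg::asVec(ri), cg::asVec(rj), cg::asVec(rk), cg::asVec(rl),
                   gi, gj, gk, gl);
  NumericMatrix out(4, 3);
  for (int d = 0; d < 3; ++d) {
    out(0, d) = gi.v[d]; out(1, d) = gj.v[d];
    out(2, d) = gk.v[d]; out(3, d) = gl.v[d];
  }
  return out;
}
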