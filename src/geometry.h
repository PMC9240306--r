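#ifndef CGMELT_GEOMETRY_H
#define CGMELT_GEOMETRY_H

#include <Rcpp.h>
#include <cmath>

namespace cg {

const double kRad2Deg = 57.29577951308232;
const double kDeg2Rad = 0.017453292519943295;
const double KB = 0.0083145; // kJ/mol/K

struct Vec3 {
  double v[3];
  Vec3() { v[0] = v[1] = v[2] = 0.0; }
};

inline Vec3 asVec(const Rcpp::NumericVector &x) {
  Vec3 r;
  r.v[0] = x[0]; r.v[1] = x[1]; r.v[2] = x[2];
  return r;
}

inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  Vec3 r;
  for (int d = 0; d < 3; ++d) r.v[d] = a.v[d] - b.v[d];
  return r;
}

inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.v[0] * b.v[0] + a.v[1] * b.v[1] + a.v[2] * b.v[2];
}

inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  Vec3 r;
  r.v[0] = a.v[1] * b.v[2] - a.v[2] * b.v[1];
  r.v[1] = a.v[2] * b.v[0] - a.v[0] * b.v[2];
  r.v[2] = a.v[0] * b.v[1] - a.v[1] * b.v[0];
  return r;
}

inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }

double angleRad(const Vec3 &ri, const Vec3 &rj, const Vec3 &rk);
void angleGrad(const Vec3 &ri, const Vec3 &rj, const Vec3 &rk,
               Vec3 &gi, Vec3 &gj, Vec3 &gk);
double dihedralRad(const Vec3 &ri, const Vec3 &rj, const Vec3 &rk,
                   const Vec3 &rl);
void dihedralGrad(const Vec3 &ri, const Vec3 &rj, const Vec3 &rk,
                  const Vec3 &rl, Vec3 &gi, Vec3 &gj, Vec3 &gk, Vec3 &gl);

// wrap an angular deviation in degrees into (-180, 180]
inline double wrapDeg(double d) {
  d = std::fmod(d, 360.0);
  if (d <= -180.0) d += 360.0;
  if (d > 180.0) d -= 360.0;
  return d;
}

} // namespace cg

#endif
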