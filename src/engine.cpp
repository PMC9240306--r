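#include <Rcpp.h>
#include "geometry.h"

using namespace Rcpp;

// Overdamped (Brownian) Euler-Maruyama integrator for a restrained bead
// chain over an implicit membrane slab.  Forces: harmonic bonds between
// consecutive beads, Gaussian angle/dihedral restraints (helical or
// extended minima), a z-Gaussian membrane well per bead, an optional
// isotropic harmonic tether (calibration runs), reflecting walls in z.
// The xy plane is treated as unbounded here; periodicity enters only in
// the minimum-image contact analysis.  Noise comes from R's RNG so a
// set.seed() in the caller makes trajectories bitwise reproducible.

static inline void addRestraintForces(const std::vector<cg::Vec3> &pos,
                                      std::vector<cg::Vec3> &frc,
                                      double Kang, double thetaMin, double sigAng,
                                      double Kdih, double phiMin, double sigDih) {
  int n = (int)pos.size();
  if (Kang > 0.0) {
    for (int t = 0; t + 2 < n; ++t) {
      double th = cg::angleRad(pos[t], pos[t + 1], pos[t + 2]) * cg::kRad2Deg;
      double dev = th - thetaMin;
      double pref = -2.0 * Kang * dev * std::exp(-dev * dev / sigAng) / sigAng;
      cg::Vec3 gi, gj, gk;
      cg::angleGrad(pos[t], pos[t + 1], pos[t + 2], gi, gj, gk);
      for (int d = 0; d < 3; ++d) {
        frc[t].v[d]     += pref * cg::kRad2Deg * gi.v[d];
        frc[t + 1].v[d] += pref * cg::kRad2Deg * gj.v[d];
        frc[t + 2].v[d] += pref * cg::kRad2Deg * gk.v[d];
      }
    }
  }
  if (Kdih > 0.0) {
    for (int t = 0; t + 3 < n; ++t) {
      double ph = cg::dihedralRad(pos[t], pos[t + 1], pos[t + 2], pos[t + 3]) * cg::kRad2Deg;
      double dev = cg::wrapDeg(ph - phiMin);
      double pref = -2.0 * Kdih * dev * std::exp(-dev * dev / sigDih) / sigDih;
      cg::Vec3 gi, gj, gk, gl;
      cg::dihedralGrad(pos[t], pos[t + 1], pos[t + 2], pos[t + 3], gi, gj, gk, gl);
      for (int d = 0; d < 3; ++d) {
        frc[t].v[d]     += pref * cg::kRad2Deg * gi.v[d];
        frc[t + 1].v[d] += pref * cg::kRad2Deg * gj.v[d];
        frc[t + 2].v[d] += pref * cg::kRad2Deg * gk.v[d];
        frc[t + 3].v[d] += pref * cg::kRad2Deg * gl.v[d];
      }
    }
  }
}

// [[Rcpp::export(name = ".runLangevinCpp")]]
NumericVector runLangevinCpp(NumericMatrix positions, int nSteps,
                             int saveInterval, double dt, double zeta,
                             double kBT, double bondK, double bondR0,
                             NumericVector restr, NumericVector membrane,
                             NumericVector tether, double zLo, double zHi) {
  int n = positions.nrow();
  double Kang = restr[0], thetaMin = restr[1], sigAng = restr[2];
  double Kdih = restr[3], phiMin = restr[4], sigDih = restr[5];
  double memEps = membrane[0], memZ0 = membrane[1], memW = membrane[2];
  double tetherK = tether[0];
  bool hasTether = tetherK > 0.0;

  std::vector<cg::Vec3> pos(n), frc(n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) pos[i].v[d] = positions(i, d);

  int nSaved = nSteps / saveInterval;
  NumericVector out(Dimension((R_xlen_t)(nSaved + 1), (R_xlen_t)n, 3));
  R_xlen_t F = nSaved + 1;
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d)
      out[0 + F * (i + (R_xlen_t)n * d)] = pos[i].v[d];

  double mob = dt / zeta;
  double sig = std::sqrt(2.0 * kBT * dt / zeta);
  int saved = 0;

  for (int step = 1; step <= nSteps; ++step) {
    for (int i = 0; i < n; ++i) frc[i] = cg::Vec3();

    if (bondK > 0.0) {
      for (int b = 0; b + 1 < n; ++b) {
        cg::Vec3 dvec = cg::sub(pos[b + 1], pos[b]);
        double r = cg::norm(dvec);
        double f = bondK * (r - bondR0) / std::max(r, 1e-12);
        for (int d = 0; d < 3; ++d) {
          frc[b].v[d]     += f * dvec.v[d];
          frc[b + 1].v[d] -= f * dvec.v[d];
        }
      }
    }

    addRestraintForces(pos, frc, Kang, thetaMin, sigAng, Kdih, phiMin, sigDih);

    for (int i = 0; i < n; ++i) {
      if (memEps > 0.0) {
        double dz = pos[i].v[2] - memZ0;
        frc[i].v[2] += -memEps * dz / (memW * memW) *
                       std::exp(-dz * dz / (2.0 * memW * memW));
      }
      if (hasTether)
        for (int d = 0; d < 3; ++d)
          frc[i].v[d] += -tetherK * (pos[i].v[d] - tether[1 + d]);
    }

    for (int i = 0; i < n; ++i) {
      for (int d = 0; d < 3; ++d) {
        double f = frc[i].v[d];
        if (!std::isfinite(f))
          stop("non-finite force on bead %d at step %d", i + 1, step);
        double x = pos[i].v[d] + mob * f;
        if (kBT > 0.0) x += sig * norm_rand();
        if (d == 2) { // reflecting z walls
          while (x < zLo || x > zHi) {
            if (x < zLo) x = 2.0 * zLo - x;
            if (x > zHi) x = 2.0 * zHi - x;
          }
        }
        pos[i].v[d] = x;
      }
    }

    if (step % saveInterval == 0 && saved < nSaved) {
      ++saved;
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          out[saved + F * (i + (R_xlen_t)n * d)] = pos[i].v[d];
    }
  }
  return out;
}

// Per-frame, per-residue contact indicator: 1 if the minimum distance from
// the residue bead to any phosphate bead (minimum image in xy, plain z) is
// below the threshold.  peptide has dim (frames, beads, 3).
// [[Rcpp::export(name = ".contactMatrixCpp")]]
IntegerMatrix contactMatrixCpp(NumericVector peptide, NumericMatrix phos,
                               double Lx, double Ly, double threshold) {
  IntegerVector dims = peptide.attr("dim");
  R_xlen_t F = dims[0];
  int n = dims[1], np = phos.nrow();
  double thr2 = threshold * threshold;
  IntegerMatrix out((int)F, n);
  for (R_xlen_t f = 0; f < F; ++f) {
    for (int i = 0; i < n; ++i) {
      double x = peptide[f + F * (i + (R_xlen_t)n * 0)];
      double y = peptide[f + F * (i + (R_xlen_t)n * 1)];
      double z = peptide[f + F * (i + (R_xlen_t)n * 2)];
      int hit = 0;
      for (int p = 0; p < np; ++p) {
        double dz = z - phos(p, 2);
        double dz2 = dz * dz;
        if (dz2 > thr2) continue;
        double dx = x - phos(p, 0);
        double dy = y - phos(p, 1);
        if (Lx > 0.0) dx -= Lx * std::round(dx / Lx);
        if (Ly > 0.0) dy -= Ly * std::round(dy / Ly);
        if (dx * dx + dy * dy + dz2 < thr2) { hit = 1; break; }
      }
      out((int)f, i) = hit;
    }
  }
  return out;
}

// Two-state Markov z-trace: per-frame transition probabilities pOn
// (unbound->bound) and pOff (bound->unbound); initial state Bernoulli at
// the stationary occupancy.  Uses R's RNG.
// [[Rcpp::export(name = ".twoStateTraceCpp")]]
NumericVector twoStateTraceCpp(int nFrames, double pOn, double pOff,
                               double boundZ, double unboundZ) {
  double occ = pOn / (pOn + pOff);
  NumericVector z(nFrames);
  int s = (unif_rand() < occ) ? 1 : 0;
  z[0] = s ? boundZ : unboundZ;
  for (int f = 1; f < nFrames; ++f) {
    double u = unif_rand();
    if (s == 1) { if (u < pOff) s = 0; }
    else        { if (u < pOn)  s = 1; }
    z[f] = s ? boundZ : unboundZ;
  }
  return z;
}
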