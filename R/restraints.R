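#' Angle between three consecutive beads
#'
#' The backbone angle theta_ijk is the angle at the central bead j between
#' the arms j->i and j->k, in degrees.
#'
#' @param ri,rj,rk 3-vectors, nm.
#' @return Angle in degrees, in [0, 180].
#' @examples
#' computeAngle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)) # 90
#' @export
computeAngle <- function(ri, rj, rk) {
  .checkVec3(ri, "ri"); .checkVec3(rj, "rj"); .checkVec3(rk, "rk")
  if (all(ri == rj) || all(rk == rj))
    stop("degenerate geometry: coincident points in angle triplet (ri/rk vs rj)")
  .angleCpp(ri, rj, rk)
}

#' Four-quadrant dihedral of four consecutive beads
#'
#' The dihedral phi_ijkl around the j-k axis, computed via the
#' four-quadrant inverse tangent of its sine and cosine, in degrees within
#' (-180, 180].  Planar cis gives 0, planar trans 180; mirror images have
#' opposite sign.
#'
#' @param ri,rj,rk,rl 3-vectors, nm.
#' @return Dihedral in degrees.
#' @export
computeDihedral <- function(ri, rj, rk, rl) {
  .checkVec3(ri, "ri"); .checkVec3(rj, "rj")
  .checkVec3(rk, "rk"); .checkVec3(rl, "rl")
  .dihedralCpp(ri, rj, rk, rl)
}

.checkVec3 <- function(x, name) {
  if (!is.numeric(x) || length(x) != 3 || !all(is.finite(x)))
    stop(sprintf("%s must be a finite numeric 3-vector (nm)", name))
  invisible(x)
}

#' Gaussian angle restraint energy
#'
#' \eqn{V_\theta = -K e^{-(\theta - \theta_{min})^2 / \sigma}} with theta in
#' degrees and sigma in degrees^2.  The well bottom is exactly -K at
#' theta = thetaMin and the energy decays to zero in the tails.
#'
#' @param theta angle(s), degrees.
#' @param p a [RestraintParams-class].
#' @return Energy in kJ/mol (vectorised over `theta`).
#' @export
angleRestraintEnergy <- function(theta, p) {
  stopifnot(is(p, "RestraintParams"))
  validObject(p)
  dev <- theta - p@thetaMin
  -p@Kangle * exp(-dev^2 / p@sigmaAngle)
}

#' Gaussian dihedral restraint energy
#'
#' As [angleRestraintEnergy()] for the dihedral term; the deviation
#' phi - phiMin is wrapped into (-180, 180] before squaring so the
#' potential is periodic and has no cliff at +/-180 degrees.
#'
#' @param phi dihedral(s), degrees.
#' @param p a [RestraintParams-class].
#' @return Energy in kJ/mol (vectorised over `phi`).
#' @export
dihedralRestraintEnergy <- function(phi, p) {
  stopifnot(is(p, "RestraintParams"))
  validObject(p)
  dev <- .wrapDeg(phi - p@phiMin)
  -p@Kdihedral * exp(-dev^2 / p@sigmaDihedral)
}

# Gaussian restraint force prefactor dV/d(angle in degrees), kJ/mol/deg
.gaussPrefactor <- function(dev, K, sigma) {
  2 * K * dev * exp(-dev^2 / sigma) / sigma
}

#' Analytic force of the angle restraint
#'
#' Returns the Cartesian forces on beads i, j, k from the Gaussian angle
#' restraint: \eqn{F = -dV/d\theta \cdot d\theta/dr}.  Forces sum to zero
#' and vanish at theta = thetaMin.
#'
#' @param ri,rj,rk 3-vectors, nm.
#' @param p a [RestraintParams-class].
#' @return 3 x 3 matrix; rows are the forces on i, j, k in kJ/mol/nm.
#' @export
angleRestraintForce <- function(ri, rj, rk, p) {
  stopifnot(is(p, "RestraintParams"))
  theta <- computeAngle(ri, rj, rk)
  dVdtheta <- .gaussPrefactor(theta - p@thetaMin, p@Kangle, p@sigmaAngle)
  grad <- .angleGradCpp(ri, rj, rk) # d(theta rad)/dr
  f <- -dVdtheta * (180 / pi) * grad
  dimnames(f) <- list(c("i", "j", "k"), c("x", "y", "z"))
  f
}

#' Analytic force of the dihedral restraint
#'
#' @param ri,rj,rk,rl 3-vectors, nm.
#' @param p a [RestraintParams-class].
#' @return 4 x 3 matrix; rows are the forces on i, j, k, l in kJ/mol/nm.
#' @export
dihedralRestraintForce <- function(ri, rj, rk, rl, p) {
  stopifnot(is(p, "RestraintParams"))
  phi <- computeDihedral(ri, rj, rk, rl)
  dev <- .wrapDeg(phi - p@phiMin)
  dVdphi <- .gaussPrefactor(dev, p@Kdihedral, p@sigmaDihedral)
  grad <- .dihedralGradCpp(ri, rj, rk, rl) # d(phi rad)/dr
  f <- -dVdphi * (180 / pi) * grad
  dimnames(f) <- list(c("i", "j", "k", "l"), c("x", "y", "z"))
  f
}

#' Total restraint energy of a bead chain
#'
#' Evaluates one Gaussian angle term per consecutive bead triplet and one
#' Gaussian dihedral term per consecutive quadruplet (n - 2 and n - 3
#' terms for an n-bead chain).
#'
#' @param chain a [BeadChain-class] with at least 4 beads.
#' @param p a [RestraintParams-class].
#' @return A [RestraintEnergyReport-class]; its `total` equals the sum of
#'   all itemised terms.
#' @examples
#' ch <- genPeptideChain(state = "helical")
#' chainRestraintEnergy(ch, restraintParams("helical"))@total
#' @export
chainRestraintEnergy <- function(chain, p) {
  stopifnot(is(chain, "BeadChain"), is(p, "RestraintParams"))
  validObject(chain)
  pos <- chain@positions
  n <- nrow(pos)
  if (n < 4) stop("chain too short: need >= 4 beads for angle and dihedral terms")
  theta <- vapply(seq_len(n - 2), function(t)
    computeAngle(pos[t, ], pos[t + 1, ], pos[t + 2, ]), numeric(1))
  phi <- vapply(seq_len(n - 3), function(t)
    computeDihedral(pos[t, ], pos[t + 1, ], pos[t + 2, ], pos[t + 3, ]),
    numeric(1))
  aTerms <- data.frame(first = seq_len(n - 2), theta = theta,
                       energy = angleRestraintEnergy(theta, p))
  dTerms <- data.frame(first = seq_len(n - 3), phi = phi,
                       energy = dihedralRestraintEnergy(phi, p))
  new("RestraintEnergyReport",
      total = sum(aTerms$energy) + sum(dTerms$energy),
      angleTerms = aTerms, dihedralTerms = dTerms)
}
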