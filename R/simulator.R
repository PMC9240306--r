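#' Implicit membrane energy and force on one bead
#'
#' The slab is an attractive z-Gaussian well,
#' \eqn{U(z) = -\epsilon \exp(-(z - z_0)^2 / (2 w^2))}, with minimum
#' -wellDepth on the phosphate plane and vanishing far from it.
#'
#' @param z bead height(s), nm.
#' @param m a [MembraneModel-class].
#' @return A list with `energy` (kJ/mol) and `force` (dU/dz negated,
#'   kJ/mol/nm), each vectorised over `z`.
#' @export
membraneEnergyForce <- function(z, m) {
  stopifnot(is(m, "MembraneModel"))
  validObject(m)
  dz <- z - m@planeZ
  g <- exp(-dz^2 / (2 * m@wellWidth^2))
  list(energy = -m@wellDepth * g,
       force = -m@wellDepth * dz * g / m@wellWidth^2)
}

#' One overdamped Langevin (Euler-Maruyama) update
#'
#' Positions advance by \eqn{F \Delta t / \zeta} plus Gaussian noise of
#' per-coordinate variance \eqn{2 k_B T \Delta t / \zeta}, where the drag
#' is \eqn{\zeta = m \gamma} (beadMass times friction).  The caller's RNG
#' state drives the noise, so `set.seed()` makes the update reproducible.
#'
#' @param positions n x 3 matrix, nm.
#' @param forces n x 3 matrix, kJ/mol/nm.
#' @param cfg a [SimulationConfig-class].
#' @return Updated n x 3 position matrix.
#' @export
langevinStep <- function(positions, forces, cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  positions <- as.matrix(positions); forces <- as.matrix(forces)
  if (!identical(dim(positions), dim(forces)))
    stop("positions and forces must have identical dimensions")
  if (!all(is.finite(forces))) stop("non-finite force passed to langevinStep")
  zeta <- cfg@beadMass * cfg@friction
  out <- positions + forces * cfg@dt / zeta
  if (cfg@temperature > 0)
    out <- out + matrix(rnorm(length(positions),
                              sd = sqrt(2 * .kB * cfg@temperature * cfg@dt / zeta)),
                        nrow = nrow(positions))
  out
}

# lattice of static phosphate beads covering the xy box at planeZ
.phosphateLattice <- function(box, planeZ, spacing = 0.8) {
  nx <- max(1L, round(box[1] / spacing))
  ny <- max(1L, round(box[2] / spacing))
  g <- expand.grid(x = (seq_len(nx) - 0.5) * box[1] / nx,
                   y = (seq_len(ny) - 0.5) * box[2] / ny)
  cbind(x = g$x, y = g$y, z = rep(planeZ, nrow(g)))
}

#' Run a restrained-chain trajectory over the implicit membrane
#'
#' Integrates the chain with overdamped Langevin dynamics under harmonic
#' bonds, the per-state Gaussian angle/dihedral restraints, and the
#' membrane z-well; z is confined by reflecting walls at the box faces
#' while xy is unbounded (periodicity applies in the contact analysis).
#' Before integration the chain is translated so its centre of mass sits
#' `startDistance` above the phosphate plane, mirroring the study's
#' starting geometry (4.0 nm).
#'
#' @param chain a [BeadChain-class].
#' @param m a [MembraneModel-class].
#' @param cfg a [SimulationConfig-class].
#' @param p optional [RestraintParams-class]; `NULL` disables restraints.
#' @param startDistance initial COM height above the phosphate plane, nm.
#' @param phosphateSpacing lattice spacing of the static phosphate plane
#'   recorded for the contact analysis, nm.
#' @return A [Trajectory-class] of `1 + nSteps %/% saveInterval` frames
#'   (initial frame included), with seed/temperature provenance.
#' @export
runTrajectory <- function(chain, m, cfg, p = NULL, startDistance = 4,
                          phosphateSpacing = 0.8) {
  stopifnot(is(chain, "BeadChain"), is(m, "MembraneModel"),
            is(cfg, "SimulationConfig"))
  validObject(chain); validObject(m); validObject(cfg)
  pos <- chain@positions
  pos[, 1] <- pos[, 1] - mean(pos[, 1]) + m@box[1] / 2
  pos[, 2] <- pos[, 2] - mean(pos[, 2]) + m@box[2] / 2
  pos[, 3] <- pos[, 3] - mean(pos[, 3]) + m@planeZ + startDistance
  if (any(pos[, 3] < 0 | pos[, 3] > m@box[3]))
    stop("starting chain extends outside the box in z; enlarge the box or lower startDistance")
  restr <- if (is.null(p)) rep(0, 6) else {
    stopifnot(is(p, "RestraintParams")); validObject(p)
    c(p@Kangle, p@thetaMin, p@sigmaAngle, p@Kdihedral, p@phiMin, p@sigmaDihedral)
  }
  if (!is.null(p) && p@sigmaAngle <= 0) stop("invalid restraint parameters")
  zeta <- cfg@beadMass * cfg@friction
  set.seed(cfg@seed)
  frames <- .runLangevinCpp(pos, cfg@nSteps, cfg@saveInterval, cfg@dt, zeta,
                            .kB * cfg@temperature, cfg@bondK, cfg@bondR0,
                            restr, c(m@wellDepth, m@planeZ, m@wellWidth),
                            c(0, 0, 0, 0), 0, m@box[3])
  trajectory(frames, .phosphateLattice(m@box, m@planeZ, phosphateSpacing),
             chain@residueIds, cfg@temperature, m@box,
             provenance = list(engine = "overdamped-langevin", seed = cfg@seed,
                               dt = cfg@dt, friction = cfg@friction,
                               beadMass = cfg@beadMass, nSteps = cfg@nSteps,
                               state = chain@state,
                               startDistance = startDistance))
}

# single-bead sampling of an analytic 1-D potential; used by calibration
# tests (harmonic tether or the membrane well itself)
.sampleBead1D <- function(cfg, m = NULL, tetherK = 0, tetherPoint = c(0, 0, 0),
                          z0 = NULL, zLim = c(-Inf, Inf)) {
  zeta <- cfg@beadMass * cfg@friction
  start <- matrix(if (is.null(z0)) tetherPoint else c(tetherPoint[1:2], z0), 1, 3)
  mem <- if (is.null(m)) c(0, 0, 1) else c(m@wellDepth, m@planeZ, m@wellWidth)
  if (is.null(m)) { zlo <- -1e6; zhi <- 1e6 } else { zlo <- 0; zhi <- m@box[3] }
  if (is.finite(zLim[1])) zlo <- zLim[1]
  if (is.finite(zLim[2])) zhi <- zLim[2]
  set.seed(cfg@seed)
  frames <- .runLangevinCpp(start, cfg@nSteps, cfg@saveInterval, cfg@dt, zeta,
                            .kB * cfg@temperature, 0, cfg@bondR0,
                            rep(0, 6), mem, c(tetherK, tetherPoint), zlo, zhi)
  matrix(frames, ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
}

#' Run one trajectory per temperature of a ladder
#'
#' Mirrors the study's protocol of independent runs across 310-450 K in
#' 10 K steps (15 temperatures).  Each run uses a seed derived from the
#' base seed so the ladder is reproducible yet its members independent.
#'
#' @param chain,m,p,cfgBase as in [runTrajectory()].
#' @param temps temperatures, K; default `seq(310, 450, by = 10)`.
#' @param ... passed on to [runTrajectory()].
#' @return A list of [Trajectory-class] objects, one per temperature.
#' @export
runTemperatureLadder <- function(chain, m, cfgBase, p = NULL,
                                 temps = seq(310, 450, by = 10), ...) {
  if (!length(temps)) stop("temps must be nonempty")
  lapply(seq_along(temps), function(i) {
    cfg <- cfgBase
    cfg@temperature <- temps[i]
    cfg@seed <- cfgBase@seed + 1000L * i
    runTrajectory(chain, m, cfg, p = p, ...)
  })
}
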