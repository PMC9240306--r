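# Ground-truth generators.  Every generator is a pure function of its
# seed and embeds its ground truth in the trajectory provenance (or as a
# "truth" attribute), so tests score recovery without re-deriving it.

# residue xy positions on (and phosphate lattice under) a square grid,
# one residue directly above a phosphate so contact is governed by z alone
.contactLattice <- function(nRes, spacing = 0.8, planeZ = 1) {
  side <- ceiling(sqrt(nRes))
  g <- expand.grid(x = (seq_len(side) - 0.5) * spacing,
                   y = (seq_len(side) - 0.5) * spacing)
  list(phos = cbind(x = g$x, y = g$y, z = planeZ),
       xy = as.matrix(g[((seq_len(nRes) - 1) %% nrow(g)) + 1, ]),
       box = c(side * spacing, side * spacing, 6))
}

#' Two-state Markov binding trajectory
#'
#' Each residue's bead toggles between a bound height (`boundZ` above the
#' phosphate plane, inside the 1 nm contact shell) and an unbound height
#' via an independent two-state Markov chain with per-frame transition
#' probabilities.  The stationary occupancy equals the requested
#' occupancy (or kOn/(kOn + kOff) when rates are given); initial states
#' are drawn from the stationary law, so the chain is stationary from
#' frame one.  Beads sit directly above lattice phosphates, making the
#' minimum protein-phosphate distance exactly the z offset.
#'
#' @param occupancy target bound fraction, scalar or one value per
#'   residue, each in \[0, 1\].  Ignored when both rates are supplied.
#' @param nFrames number of frames.
#' @param seed RNG seed.
#' @param kOn,kOff optional per-frame transition probabilities
#'   (unbound to bound / bound to unbound).
#' @param switchRate total per-frame switching probability used to convert
#'   an occupancy into rates: kOn = switchRate x occupancy, kOff =
#'   switchRate x (1 - occupancy); the chain then decorrelates over about
#'   1/switchRate frames.
#' @param residueIds residue numbers (default the studied segment 65:97).
#' @param boundZ,unboundZ heights above the phosphate plane, nm; must lie
#'   strictly inside/outside the 1 nm contact threshold.
#' @param temperature nominal K stored on the trajectory.
#' @return A [Trajectory-class]; `provenance$truth` carries the exact
#'   per-residue occupancies.
#' @examples
#' tr <- genMarkovBindingTrajectory(0.6, nFrames = 500, seed = 7)
#' globalContactIndex(contactProfile(tr))
#' @export
genMarkovBindingTrajectory <- function(occupancy = 0.5, nFrames, seed,
                                       kOn = NULL, kOff = NULL,
                                       switchRate = 0.5,
                                       residueIds = 65:97,
                                       boundZ = 0.5, unboundZ = 3,
                                       temperature = 310) {
  nRes <- length(residueIds)
  if (boundZ >= 1 || boundZ < 0 || unboundZ <= 1)
    stop("boundZ must lie in [0, 1) and unboundZ above 1 nm (contact threshold)")
  if (!is.null(kOn) && !is.null(kOff)) {
    if (any(c(kOn, kOff) < 0) || all(c(kOn, kOff) == 0))
      stop("invalid rates: kOn, kOff must be >= 0 and not both zero")
    occupancy <- kOn / (kOn + kOff)
    pOn <- rep_len(kOn, nRes); pOff <- rep_len(kOff, nRes)
  } else {
    if (any(occupancy < 0 | occupancy > 1))
      stop("occupancy must lie in [0, 1]")
    occupancy <- rep_len(occupancy, nRes)
    pOn <- switchRate * occupancy
    pOff <- switchRate * (1 - occupancy)
  }
  occupancy <- rep_len(occupancy, nRes)
  lat <- .contactLattice(nRes)
  planeZ <- lat$phos[1, 3]
  set.seed(seed)
  pept <- array(0, dim = c(nFrames, nRes, 3))
  for (r in seq_len(nRes)) {
    pept[, r, 1] <- lat$xy[r, 1]
    pept[, r, 2] <- lat$xy[r, 2]
    pept[, r, 3] <- planeZ + .twoStateTraceCpp(nFrames, pOn[r], pOff[r],
                                               boundZ, unboundZ)
  }
  trajectory(pept, lat$phos, residueIds, temperature, lat$box,
             provenance = list(generator = "two-state-markov", seed = seed,
                               truth = list(occupancy = occupancy,
                                            switchRate = switchRate)))
}

#' Temperature-ladder ensemble with a prescribed melting midpoint
#'
#' Builds one two-state trajectory per ladder temperature with occupancy
#' following the logistic \eqn{1 / (1 + e^{(T - T_m)/width})}, so the
#' ensemble's melting curve has a known midpoint.  The default ladder is
#' the study's: 310-450 K in 10 K steps (15 temperatures).
#'
#' @param Tm melting midpoint, K.
#' @param width logistic width, K (> 0 for a smooth curve; a tiny width
#'   approaches a step function).
#' @param temps ladder temperatures, K.
#' @param nFrames frames per temperature.
#' @param seed base seed; run i uses seed + i.
#' @param ... passed to [genMarkovBindingTrajectory()].
#' @return List of [Trajectory-class]; attribute `"truth"` records Tm,
#'   width and the per-temperature occupancies.
#' @export
genMeltingEnsemble <- function(Tm = 372, width = 15,
                               temps = seq(310, 450, by = 10),
                               nFrames = 2000, seed = 1, ...) {
  if (width <= 0) stop("width must be > 0 (K)")
  occ <- 1 / (1 + exp((temps - Tm) / width))
  out <- lapply(seq_along(temps), function(i) {
    tr <- genMarkovBindingTrajectory(occ[i], nFrames = nFrames,
                                     seed = seed + i,
                                     temperature = temps[i], ...)
    tr@provenance$truth$Tm <- Tm
    tr@provenance$truth$width <- width
    tr
  })
  attr(out, "truth") <- list(Tm = Tm, width = width, occupancy = occ,
                             temps = temps)
  out
}

#' Biased Boltzmann samples from an analytic free-energy profile
#'
#' Draws exact, uncorrelated samples from
#' \eqn{\rho_i(\xi) \propto e^{-(U(\xi) + \frac{1}{2} k (\xi - \xi_i)^2)/k_BT}}
#' for each umbrella centre by inverse-CDF sampling on a 1e-4 nm grid,
#' so WHAM recovery error is purely statistical.  The default centres
#' mirror the study's umbrella protocol: 11 windows evenly spanning a
#' 1.2 nm path starting at the profile's minimum.
#'
#' @param pmf an [AnalyticPMF-class] ground truth.
#' @param centers window centres, nm.
#' @param k harmonic force constant, kJ/mol/nm^2.
#' @param temperature K.
#' @param nPerWindow samples per window.
#' @param seed RNG seed.
#' @return List of [UmbrellaWindow-class]; attribute `"truth"` records the
#'   profile, temperature and seed.
#' @export
genUmbrellaSamples <- function(pmf, centers = NULL, k = 1000,
                               temperature = 300, nPerWindow = 1000,
                               seed = 1) {
  stopifnot(is(pmf, "AnalyticPMF"))
  validObject(pmf)
  if (is.null(centers))
    centers <- seq(pmf@location, pmf@location + 1.2, length.out = 11)
  if (any(centers < pmf@domain[1] | centers > pmf@domain[2]))
    stop("window centers must lie inside the profile domain")
  step <- 1e-4
  grid <- seq(pmf@domain[1], pmf@domain[2], by = step)
  U <- evalPMF(pmf, grid)
  kT <- .kB * temperature
  set.seed(seed)
  out <- lapply(centers, function(c0) {
    logw <- -(U + 0.5 * k * (grid - c0)^2) / kT
    w <- exp(logw - max(logw))
    cdf <- cumsum(w)
    tot <- cdf[length(cdf)]
    if (!is.finite(tot) || tot <= 0)
      stop("unnormalizable biased density for window at ", c0, " nm")
    u <- runif(nPerWindow) * tot
    xi <- grid[findInterval(u, cdf) + 1] + runif(nPerWindow, 0, step) - step / 2
    umbrellaWindow(c0, xi, k)
  })
  attr(out, "truth") <- list(pmf = pmf, temperature = temperature,
                             k = k, seed = seed)
  out
}

#' Toy bilayer patch matching the study's composition
#'
#' Places labelled phosphate beads on a jittered square lattice in two
#' leaflet planes.  Defaults mirror the simulated system: 167 lipids per
#' leaflet in a DOPE:DOPS:DOPC 84:50:33 (5:3:2) ratio, i.e. 334 phosphate
#' beads in total.  Lipid identity affects labels only; the contact
#' analysis treats all phosphates identically.
#'
#' @param nPerLeaflet lipids per leaflet.
#' @param composition named integer vector of lipid counts; must sum to
#'   `nPerLeaflet`.
#' @param area leaflet area, nm^2 (default 0.64 nm^2 per lipid).
#' @param upperZ upper phosphate plane, nm.
#' @param thickness phosphate-to-phosphate bilayer thickness, nm.
#' @param jitter xy lattice jitter standard deviation, nm.
#' @param seed RNG seed for the jitter.
#' @return data.frame with columns `x`, `y`, `z` (nm), `lipid`, `leaflet`;
#'   attribute `"box"` carries (Lx, Ly, Lz).
#' @examples
#' nrow(genBilayerPatch()) # 334
#' @export
genBilayerPatch <- function(nPerLeaflet = 167,
                            composition = c(DOPE = 84, DOPS = 50, DOPC = 33),
                            area = NULL, upperZ = 2, thickness = 3.8,
                            jitter = 0.08, seed = 1) {
  if (sum(composition) != nPerLeaflet)
    stop(sprintf("composition sums to %d, not nPerLeaflet = %d",
                 sum(composition), nPerLeaflet))
  if (is.null(area)) area <- 0.64 * nPerLeaflet
  L <- sqrt(area)
  side <- ceiling(sqrt(nPerLeaflet))
  g <- expand.grid(x = (seq_len(side) - 0.5) * L / side,
                   y = (seq_len(side) - 0.5) * L / side)[seq_len(nPerLeaflet), ]
  labels <- rep(names(composition), composition)
  set.seed(seed)
  one <- function(z, leaflet) data.frame(
    x = (g$x + rnorm(nPerLeaflet, sd = jitter)) %% L,
    y = (g$y + rnorm(nPerLeaflet, sd = jitter)) %% L,
    z = z, lipid = labels, leaflet = leaflet)
  out <- rbind(one(upperZ, "upper"), one(upperZ - thickness, "lower"))
  attr(out, "box") <- c(L, L, upperZ + 6)
  out
}

# NeRF bead placement: distance r to C, angle theta (deg) at C with B,
# dihedral phi (deg) about B-C with A
.placeBead <- function(A, B, C, r, thetaDeg, phiDeg) {
  th <- thetaDeg * pi / 180; ph <- phiDeg * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) stop("collinear reference beads in chain construction")
  n <- n / nn
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  C + r * (-cos(th) * bc + sin(th) * cos(ph) * m + sin(th) * sin(ph) * n)
}

#' Ideal-geometry peptide chain
#'
#' Builds a bead chain whose every consecutive angle equals thetaMin and
#' every dihedral phiMin of the active restraint parameters, so the chain
#' sits exactly at the global minimum of [chainRestraintEnergy()]:
#' -(n-2) Kangle - (n-3) Kdihedral.  The chain is aligned with its
#' principal axis along x and translated so its centre of mass lies
#' `startDistance` above the phosphate plane, the study's starting
#' geometry being 4.0 nm.
#'
#' @param residueRange residue numbers, e.g. `65:97` (the default, 33
#'   beads).
#' @param state `"helical"` or `"extended"`.
#' @param p restraint parameters; default [restraintParams()] for `state`.
#' @param startDistance COM height above `planeZ`, nm.
#' @param planeZ phosphate plane height, nm.
#' @param bondLength consecutive-bead distance, nm.
#' @return A [BeadChain-class].
#' @export
genPeptideChain <- function(residueRange = 65:97,
                            state = c("helical", "extended"), p = NULL,
                            startDistance = 4, planeZ = 0,
                            bondLength = 0.35) {
  state <- match.arg(state)
  if (!length(residueRange)) stop("empty residue range")
  if (is.null(p)) p <- restraintParams(state)
  n <- length(residueRange)
  if (n < 4) stop("need >= 4 residues for a restrained chain")
  th <- p@thetaMin; ph <- p@phiMin; r <- bondLength
  pos <- matrix(0, n, 3)
  pos[2, ] <- c(r, 0, 0)
  pos[3, ] <- pos[2, ] + r * c(-cos(th * pi / 180), sin(th * pi / 180), 0)
  for (i in 4:n)
    pos[i, ] <- .placeBead(pos[i - 3, ], pos[i - 2, ], pos[i - 1, ], r, th, ph)
  # principal axis along x, COM at the requested height
  pc <- prcomp(pos, center = TRUE)
  ax <- pc$rotation[, 1]
  # rotation taking the principal axis onto x (Rodrigues)
  v <- c(0, -ax[3], ax[2]) # ax x ex
  s <- sqrt(sum(v^2)); cth <- ax[1]
  R <- diag(3)
  if (s > 1e-12) {
    K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                byrow = TRUE)
    R <- diag(3) + K + K %*% K * ((1 - cth) / s^2)
  }
  pos <- sweep(pos, 2, colMeans(pos)) %*% t(R)
  pos[, 3] <- pos[, 3] - mean(pos[, 3]) + planeZ + startDistance
  beadChain(pos, residueIds = residueRange, state = state)
}

#' Exact single-bead contact occupancy of the implicit membrane
#'
#' Boltzmann quadrature oracle, independent of the Langevin engine: for
#' one bead in the membrane z-well with reflecting walls and a square
#' phosphate lattice of given spacing, the probability that the minimum
#' bead-phosphate distance is below the threshold is
#' \deqn{\int f(z) e^{-U(z)/k_BT} dz / \int e^{-U(z)/k_BT} dz,}
#' where f(z) is the fraction of the lattice unit cell within the contact
#' shell at height z (computed geometrically).  Used to predict melting
#' behaviour of unbonded chains exactly.
#'
#' @param m a [MembraneModel-class].
#' @param temperature K.
#' @param threshold contact cutoff, nm.
#' @param spacing phosphate lattice spacing, nm.
#' @param nz quadrature points in z.
#' @return Occupancy in \[0, 1\].
#' @export
analyticContactOccupancy <- function(m, temperature, threshold = 1,
                                     spacing = 0.8, nz = 2001) {
  stopifnot(is(m, "MembraneModel"))
  kT <- .kB * temperature
  z <- seq(0, m@box[3], length.out = nz)
  rho <- exp(-membraneEnergyForce(z, m)$energy / kT)
  # xy unit cell fraction within sqrt(thr^2 - dz^2) of the nearest
  # lattice site (offsets uniform over [-s/2, s/2]^2)
  s <- spacing
  u <- seq(-s / 2, s / 2, length.out = 101)
  cell <- expand.grid(ux = u, uy = u)
  d2 <- cell$ux^2 + cell$uy^2
  f <- vapply(z, function(zi) {
    h2 <- threshold^2 - (zi - m@planeZ)^2
    if (h2 <= 0) 0 else mean(d2 < h2)
  }, numeric(1))
  sum(f * rho) / sum(rho)
}

#' Analytic melting midpoint of the implicit-membrane two-state system
#'
#' Predicts the melting temperature of the exact Boltzmann occupancy
#' curve from [analyticContactOccupancy()].  `method = "fit"` applies the
#' same four-parameter logistic estimator the pipeline uses
#' ([fitMeltingTemperature()]) to the exact occupancies on the ladder, so
#' simulated and predicted midpoints are compared estimator-to-estimator;
#' `method = "crossing"` instead returns the temperature at which the
#' occupancy crosses the midpoint between its values at the ladder ends.
#'
#' @inheritParams analyticContactOccupancy
#' @param temps ladder temperatures, K.
#' @param method `"fit"` (default) or `"crossing"`.
#' @return Temperature, K.
#' @export
analyticMeltingTemperature <- function(m, temps = seq(310, 450, by = 10),
                                       threshold = 1, spacing = 0.8,
                                       method = c("fit", "crossing")) {
  method <- match.arg(method)
  occT <- function(T) analyticContactOccupancy(m, T, threshold, spacing)
  if (method == "fit") {
    occ <- vapply(temps, occT, numeric(1))
    cv <- new("MeltingCurve", temperature = temps, index = occ, fit = list())
    return(meltingFit(fitMeltingTemperature(cv))$Tm)
  }
  lo <- occT(min(temps)); hi <- occT(max(temps))
  stats::uniroot(function(T) occT(T) - (lo + hi) / 2, range(temps),
                 tol = 0.01)$root
}
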