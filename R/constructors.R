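#' Create restraint parameters
#'
#' The study's force field defers the numeric restraint parameters to prior
#' parameterisation work; the defaults shipped here (helical: thetaMin 96,
#' phiMin -120; extended: thetaMin 127, phiMin 180; K 10 kJ/mol, sigma 200
#' degrees^2 throughout) are documented illustrative placeholders and
#' should be overridden per run when calibrated values are available.
#'
#' @param state `"helical"` or `"extended"`.
#' @param Kangle,Kdihedral well depths, kJ/mol.
#' @param thetaMin angle minimum, degrees.
#' @param sigmaAngle,sigmaDihedral Gaussian widths, degrees^2.
#' @param phiMin dihedral minimum, degrees.
#' @return A [RestraintParams-class] object.
#' @examples
#' restraintParams("helical")
#' restraintParams("extended", Kdihedral = 8)
#' @export
restraintParams <- function(state = c("helical", "extended"),
                            Kangle = 10, thetaMin = NULL, sigmaAngle = 200,
                            Kdihedral = 10, phiMin = NULL,
                            sigmaDihedral = 200) {
  state <- match.arg(state)
  if (is.null(thetaMin)) thetaMin <- if (state == "helical") 96 else 127
  if (is.null(phiMin)) phiMin <- if (state == "helical") -120 else 180
  new("RestraintParams", state = state, Kangle = Kangle, thetaMin = thetaMin,
      sigmaAngle = sigmaAngle, Kdihedral = Kdihedral, phiMin = phiMin,
      sigmaDihedral = sigmaDihedral)
}

#' Create a bead chain
#'
#' @param positions n x 3 matrix of bead coordinates, nm.
#' @param residueIds integer residue numbers (default consecutive from 65,
#'   the first residue of the studied segment).
#' @param state conformational-state tag.
#' @return A [BeadChain-class] object.
#' @export
beadChain <- function(positions, residueIds = NULL,
                      state = c("helical", "extended")) {
  state <- match.arg(state)
  positions <- as.matrix(positions)
  if (is.null(residueIds)) residueIds <- seq(65, length.out = nrow(positions))
  new("BeadChain", positions = positions,
      residueIds = as.integer(residueIds), state = state)
}

#' Create an implicit membrane model
#'
#' @param planeZ mean phosphate plane, nm.
#' @param wellDepth per-bead well depth, kJ/mol.
#' @param wellWidth well width, nm.
#' @param box box lengths (Lx, Ly, Lz), nm.
#' @return A [MembraneModel-class] object.
#' @export
membraneModel <- function(planeZ = 2, wellDepth = 10, wellWidth = 0.3,
                          box = c(6, 6, 10)) {
  new("MembraneModel", planeZ = planeZ, wellDepth = wellDepth,
      wellWidth = wellWidth, box = as.numeric(box))
}

#' Create Langevin run settings
#'
#' @param dt time step, ps.
#' @param friction collision rate, 1/ps.
#' @param beadMass bead mass, amu.
#' @param temperature K.
#' @param nSteps integration steps.
#' @param saveInterval frame-saving stride.
#' @param seed RNG seed.
#' @param bondK bond force constant, kJ/mol/nm^2 (0 = unbonded beads).
#' @param bondR0 bond rest length, nm.
#' @return A [SimulationConfig-class] object.
#' @export
simulationConfig <- function(dt = 0.002, friction = 1, beadMass = 72,
                             temperature = 310, nSteps = 10000L,
                             saveInterval = 10L, seed = 1L,
                             bondK = 2000, bondR0 = 0.35) {
  new("SimulationConfig", dt = dt, friction = friction, beadMass = beadMass,
      temperature = temperature, nSteps = as.integer(nSteps),
      saveInterval = as.integer(saveInterval), seed = as.integer(seed),
      bondK = bondK, bondR0 = bondR0)
}

#' Create a trajectory object
#'
#' @param peptide (frames x beads x 3) array, nm.
#' @param phosphates static phosphate coordinates, n x 3 matrix, nm.
#' @param residueIds integer residue numbers.
#' @param temperature K.
#' @param box box lengths, nm.
#' @param provenance metadata list.
#' @return A [Trajectory-class] object.
#' @export
trajectory <- function(peptide, phosphates, residueIds, temperature,
                       box, provenance = list()) {
  new("Trajectory", peptide = peptide, phosphates = as.matrix(phosphates),
      residueIds = as.integer(residueIds), temperature = temperature,
      box = as.numeric(box), provenance = provenance)
}

#' Create an umbrella window
#'
#' @param center restraint centre xi0, nm.
#' @param samples reaction-coordinate samples, nm.
#' @param forceConstant harmonic force constant, kJ/mol/nm^2 (the study's
#'   umbrella protocol used 1000).
#' @return An [UmbrellaWindow-class] object.
#' @export
umbrellaWindow <- function(center, samples, forceConstant = 1000) {
  new("UmbrellaWindow", center = center, forceConstant = forceConstant,
      samples = as.numeric(samples))
}

#' Create an analytic free-energy profile
#'
#' @param form `"harmonic"`, `"square_well"`, `"double_well"` or
#'   `"morse_like"`.
#' @param depth D, kcal/mol.
#' @param location xi0, nm.
#' @param width w, nm.
#' @param domain evaluable (min, max), nm.
#' @return An [AnalyticPMF-class] object.
#' @seealso [evalPMF()], [genUmbrellaSamples()]
#' @export
analyticPMF <- function(form = c("harmonic", "square_well", "double_well",
                                 "morse_like"),
                        depth, location = 1, width = 0.3,
                        domain = c(location - 1, location + 1.5)) {
  form <- match.arg(form)
  new("AnalyticPMF", form = form, depth = depth, location = location,
      width = width, domain = as.numeric(domain))
}

#' Evaluate an analytic free-energy profile
#'
#' @param pmf an [AnalyticPMF-class] object.
#' @param xi reaction-coordinate values, nm.
#' @return Free energy in kJ/mol at each `xi`.
#' @examples
#' u <- analyticPMF("square_well", depth = 7.5, location = 1, width = 0.3)
#' evalPMF(u, c(1, 2))
#' @export
evalPMF <- function(pmf, xi) {
  stopifnot(is(pmf, "AnalyticPMF"))
  D <- pmf@depth * .kJperKcal
  x0 <- pmf@location
  w <- pmf@width
  switch(pmf@form,
    harmonic = D * ((xi - x0) / w)^2,
    square_well = ifelse(abs(xi - x0) < w / 2, -D, 0),
    double_well = D * (((xi - x0) / w)^2 - 1)^2 - D,
    morse_like = D * (1 - exp(-(xi - x0) / w))^2 - D)
}
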