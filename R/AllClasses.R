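#' Per-state Gaussian restraint parameters
#'
#' Holds the force constants, minima and Gaussian widths of the backbone
#' angle and dihedral restraints that lock a bead chain into one of two
#' conformational states ("helical" or "extended").  The restraining
#' potential for an angle is \eqn{V_\theta = -K e^{-(\theta-\theta_{min})^2/\sigma}}
#' and analogously for dihedrals; note \eqn{\sigma} (not \eqn{\sigma^2})
#' divides the squared deviation, so it carries units of degrees squared.
#'
#' @slot state character, `"helical"` or `"extended"`.
#' @slot Kangle angle well depth, kJ/mol (>= 0).
#' @slot thetaMin angle minimum, degrees, in (0, 180).
#' @slot sigmaAngle Gaussian width of the angle term, degrees^2 (> 0).
#' @slot Kdihedral dihedral well depth, kJ/mol (>= 0).
#' @slot phiMin dihedral minimum, degrees, in (-180, 180].
#' @slot sigmaDihedral Gaussian width of the dihedral term, degrees^2 (> 0).
#' @export
setClass("RestraintParams",
  representation(state = "character", Kangle = "numeric", thetaMin = "numeric",
                 sigmaAngle = "numeric", Kdihedral = "numeric",
                 phiMin = "numeric", sigmaDihedral = "numeric"))

setValidity("RestraintParams", function(object) {
  msg <- character()
  if (!object@state %in% c("helical", "extended"))
    msg <- c(msg, "state must be 'helical' or 'extended'")
  if (object@Kangle < 0) msg <- c(msg, "Kangle must be >= 0 (kJ/mol)")
  if (object@Kdihedral < 0) msg <- c(msg, "Kdihedral must be >= 0 (kJ/mol)")
  if (object@sigmaAngle <= 0) msg <- c(msg, "sigmaAngle must be > 0 (degrees^2)")
  if (object@sigmaDihedral <= 0) msg <- c(msg, "sigmaDihedral must be > 0 (degrees^2)")
  if (object@thetaMin <= 0 || object@thetaMin >= 180)
    msg <- c(msg, "thetaMin must lie in (0, 180) degrees")
  if (object@phiMin <= -180 || object@phiMin > 180)
    msg <- c(msg, "phiMin must lie in (-180, 180] degrees")
  if (length(msg)) msg else TRUE
})

#' Ordered backbone bead chain of a peptide segment
#'
#' @slot residueIds integer residue numbers, one per bead (e.g. 65:97).
#' @slot positions numeric matrix, one row per bead, columns x/y/z in nm.
#' @slot state conformational-state tag, `"helical"` or `"extended"`.
#' @export
setClass("BeadChain",
  representation(residueIds = "integer", positions = "matrix",
                 state = "character"))

setValidity("BeadChain", function(object) {
  msg <- character()
  n <- nrow(object@positions)
  if (n < 4) msg <- c(msg, "need >= 4 beads to define at least one dihedral")
  if (ncol(object@positions) != 3) msg <- c(msg, "positions must be an n x 3 matrix (nm)")
  if (length(object@residueIds) != n)
    msg <- c(msg, "residueIds length must equal bead count")
  if (!object@state %in% c("helical", "extended"))
    msg <- c(msg, "state must be 'helical' or 'extended'")
  if (n >= 2) {
    d <- sqrt(rowSums((object@positions[-1, , drop = FALSE] -
                       object@positions[-n, , drop = FALSE])^2))
    if (any(d <= 0)) msg <- c(msg, "consecutive beads must not coincide")
  }
  if (length(msg)) msg else TRUE
})

#' Itemised restraint energy of a bead chain
#'
#' @slot total total restraint energy, kJ/mol.
#' @slot angleTerms data.frame with columns `first` (index of the first bead
#'   of the triplet), `theta` (degrees) and `energy` (kJ/mol).
#' @slot dihedralTerms data.frame with columns `first`, `phi`, `energy`.
#' @export
setClass("RestraintEnergyReport",
  representation(total = "numeric", angleTerms = "data.frame",
                 dihedralTerms = "data.frame"))

setValidity("RestraintEnergyReport", function(object) {
  s <- sum(object@angleTerms$energy) + sum(object@dihedralTerms$energy)
  if (abs(object@total - s) > 1e-9 * max(1, abs(s)))
    return("total must equal the sum of per-term energies (1e-9 relative)")
  TRUE
})

#' Implicit membrane slab
#'
#' The bilayer is represented by a z-Gaussian attractive well of depth
#' `wellDepth` (per bead) centred on the mean phosphate plane `planeZ`,
#' inside an xy-periodic box with reflecting walls in z.
#'
#' @slot planeZ mean phosphate plane, nm.
#' @slot wellDepth per-bead well depth, kJ/mol (>= 0).
#' @slot wellWidth Gaussian width of the well, nm (> 0).
#' @slot box box lengths (Lx, Ly, Lz), nm.
#' @export
setClass("MembraneModel",
  representation(planeZ = "numeric", wellDepth = "numeric",
                 wellWidth = "numeric", box = "numeric"))

setValidity("MembraneModel", function(object) {
  msg <- character()
  if (object@wellDepth < 0) msg <- c(msg, "wellDepth must be >= 0 (kJ/mol)")
  if (object@wellWidth <= 0) msg <- c(msg, "wellWidth must be > 0 (nm)")
  if (length(object@box) != 3 || any(object@box <= 0))
    msg <- c(msg, "box must be three positive lengths (nm)")
  if (object@planeZ < 0 || object@planeZ > object@box[3])
    msg <- c(msg, "planeZ must lie inside the box (nm)")
  if (length(msg)) msg else TRUE
})

#' Overdamped Langevin run settings
#'
#' @slot dt integration time step, ps.
#' @slot friction collision rate gamma, 1/ps; the drag is gamma times the
#'   bead mass.
#' @slot beadMass bead mass, amu (one coarse backbone bead ~ 72 amu).
#' @slot temperature K.
#' @slot nSteps number of integration steps.
#' @slot saveInterval save a frame every this many steps.
#' @slot seed RNG seed.
#' @slot bondK harmonic bond force constant, kJ/mol/nm^2 (0 disables bonds).
#' @slot bondR0 bond rest length, nm.
#' @export
setClass("SimulationConfig",
  representation(dt = "numeric", friction = "numeric", beadMass = "numeric",
                 temperature = "numeric", nSteps = "integer",
                 saveInterval = "integer", seed = "integer",
                 bondK = "numeric", bondR0 = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0 (ps)")
  if (object@friction <= 0) msg <- c(msg, "friction must be > 0 (1/ps)")
  if (object@beadMass <= 0) msg <- c(msg, "beadMass must be > 0 (amu)")
  if (object@temperature <= 0) msg <- c(msg, "temperature must be > 0 (K)")
  if (object@nSteps < 1) msg <- c(msg, "nSteps must be >= 1")
  if (object@saveInterval < 1) msg <- c(msg, "saveInterval must be >= 1")
  if (object@bondK < 0) msg <- c(msg, "bondK must be >= 0 (kJ/mol/nm^2)")
  if (object@bondR0 <= 0) msg <- c(msg, "bondR0 must be > 0 (nm)")
  if (length(msg)) msg else TRUE
})

#' Bead trajectory over a static phosphate lattice
#'
#' @slot peptide numeric array (frames x beads x 3), nm.
#' @slot phosphates numeric matrix of static phosphate bead coordinates
#'   (rows x/y/z in columns), nm.
#' @slot residueIds integer, one per peptide bead.
#' @slot temperature K.
#' @slot box box lengths (Lx, Ly, Lz), nm; xy-periodic.
#' @slot provenance list of generator/engine metadata (seed, ground truth).
#' @export
setClass("Trajectory",
  representation(peptide = "array", phosphates = "matrix",
                 residueIds = "integer", temperature = "numeric",
                 box = "numeric", provenance = "list"))

setValidity("Trajectory", function(object) {
  msg <- character()
  d <- dim(object@peptide)
  if (length(d) != 3 || d[3] != 3)
    msg <- c(msg, "peptide must be a (frames x beads x 3) array")
  else {
    if (d[1] < 1) msg <- c(msg, "need at least one frame")
    if (length(object@residueIds) != d[2])
      msg <- c(msg, "residueIds length must match bead count")
  }
  if (ncol(object@phosphates) != 3)
    msg <- c(msg, "phosphates must be an n x 3 matrix")
  if (object@temperature <= 0) msg <- c(msg, "temperature must be > 0 (K)")
  if (length(object@box) != 3) msg <- c(msg, "box must have three lengths")
  if (length(msg)) msg else TRUE
})

#' Per-residue membrane contact indices at one temperature
#'
#' @slot temperature K.
#' @slot residueIds integer residue numbers.
#' @slot index contact index per residue, each in \[0, 1\].
#' @export
setClass("ContactProfile",
  representation(temperature = "numeric", residueIds = "integer",
                 index = "numeric"))

setValidity("ContactProfile", function(object) {
  msg <- character()
  if (length(object@index) != length(object@residueIds))
    msg <- c(msg, "one index per residue required")
  if (length(object@index) < 1) msg <- c(msg, "profile must be nonempty")
  if (any(object@index < 0 | object@index > 1))
    msg <- c(msg, "contact indices must lie in [0, 1]")
  if (object@temperature <= 0) msg <- c(msg, "temperature must be > 0 (K)")
  if (length(msg)) msg else TRUE
})

#' Melting curve of membrane binding
#'
#' Global contact index as a function of simulation temperature, with an
#' optional fitted logistic midpoint (see [fitMeltingTemperature()]).
#'
#' @slot temperature strictly increasing temperatures, K.
#' @slot index global contact index at each temperature, in \[0, 1\].
#' @slot fit list; empty until fitted, then carries Tm, width, plateau
#'   levels and diagnostics.
#' @export
setClass("MeltingCurve",
  representation(temperature = "numeric", index = "numeric", fit = "list"))

setValidity("MeltingCurve", function(object) {
  msg <- character()
  if (length(object@temperature) != length(object@index))
    msg <- c(msg, "temperature and index must have equal length")
  if (is.unsorted(object@temperature, strictly = TRUE))
    msg <- c(msg, "temperatures must be strictly increasing")
  if (any(object@index < 0 | object@index > 1))
    msg <- c(msg, "global contact indices must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' One umbrella-sampling window
#'
#' @slot center restraint target xi0, nm.
#' @slot forceConstant harmonic force constant k, kJ/mol/nm^2.
#' @slot samples scalar reaction-coordinate samples (COM distance), nm.
#' @export
setClass("UmbrellaWindow",
  representation(center = "numeric", forceConstant = "numeric",
                 samples = "numeric"))

setValidity("UmbrellaWindow", function(object) {
  msg <- character()
  if (object@forceConstant <= 0)
    msg <- c(msg, "forceConstant must be > 0 (kJ/mol/nm^2)")
  if (length(object@samples) < 1) msg <- c(msg, "need >= 1 sample")
  if (!all(is.finite(object@samples))) msg <- c(msg, "samples must be finite (nm)")
  if (length(msg)) msg else TRUE
})

#' Potential of mean force along the reaction coordinate
#'
#' @slot grid bin centres xi, nm.
#' @slot freeEnergy free energy per bin, kJ/mol; `NA` marks empty bins.
#' @slot counts total samples per bin.
#' @slot windowF per-window WHAM shift constants F_i, kJ/mol (F_1 = 0).
#' @slot temperature K used for the WHAM solve.
#' @slot reference description of the zeroing convention.
#' @export
setClass("PMFProfile",
  representation(grid = "numeric", freeEnergy = "numeric", counts = "numeric",
                 windowF = "numeric", temperature = "numeric",
                 reference = "character"))

setValidity("PMFProfile", function(object) {
  msg <- character()
  if (length(object@grid) != length(object@freeEnergy))
    msg <- c(msg, "grid and freeEnergy must have equal length")
  if (length(object@counts) != length(object@grid))
    msg <- c(msg, "counts must align with the grid")
  bad <- object@counts > 0 & !is.finite(object@freeEnergy)
  if (any(bad)) msg <- c(msg, "freeEnergy must be finite on occupied bins")
  if (length(msg)) msg else TRUE
})

#' Analytic free-energy profile used as sampling ground truth
#'
#' Closed-form one-dimensional profiles from which biased Boltzmann
#' samples can be drawn exactly, so WHAM recovery can be scored against a
#' known answer.  Forms: `"harmonic"` \eqn{D (\frac{\xi-\xi_0}{w})^2},
#' `"square_well"` (\eqn{-D} inside a well of full width `w`, 0 outside),
#' `"double_well"` (quartic with minima at \eqn{\xi_0 \pm w}),
#' `"morse_like"` (Morse profile of depth \eqn{D} and range `w`).
#'
#' @slot form one of `"harmonic"`, `"square_well"`, `"double_well"`,
#'   `"morse_like"`.
#' @slot depth D, kcal/mol.
#' @slot location xi0, nm.
#' @slot width w, nm.
#' @slot domain evaluable range (min, max), nm.
#' @export
setClass("AnalyticPMF",
  representation(form = "character", depth = "numeric", location = "numeric",
                 width = "numeric", domain = "numeric"))

setValidity("AnalyticPMF", function(object) {
  msg <- character()
  forms <- c("harmonic", "square_well", "double_well", "morse_like")
  if (!object@form %in% forms)
    msg <- c(msg, paste("form must be one of:", paste(forms, collapse = ", ")))
  if (object@width <= 0) msg <- c(msg, "width must be > 0 (nm)")
  if (length(object@domain) != 2 || diff(object@domain) <= 0)
    msg <- c(msg, "domain must be an increasing (min, max) pair (nm)")
  if (length(msg)) msg else TRUE
})
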