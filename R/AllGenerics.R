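#' @rdname Trajectory-class
#' @param object,x a package object.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname Trajectory-class
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname Trajectory-class
#' @export
setGeneric("temperature", function(x) standardGeneric("temperature"))

#' @rdname BeadChain-class
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname BeadChain-class
#' @export
setGeneric("residueIds", function(x) standardGeneric("residueIds"))

#' @rdname BeadChain-class
#' @export
setGeneric("conformationalState", function(x) standardGeneric("conformationalState"))

#' Global contact index
#'
#' Unweighted mean of the per-residue contact indices of a profile: the
#' scalar whose temperature dependence forms the melting curve of membrane
#' binding.
#'
#' @param x a [ContactProfile-class].
#' @return A fraction in \[0, 1\].
#' @export
setGeneric("globalContactIndex", function(x) standardGeneric("globalContactIndex"))

#' @describeIn Trajectory-class number of saved frames.
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@peptide)[1])

#' @describeIn Trajectory-class number of peptide beads/residues.
#' @export
setMethod("nResidues", "Trajectory", function(x) dim(x@peptide)[2])

#' @describeIn Trajectory-class simulation temperature, K.
#' @export
setMethod("temperature", "Trajectory", function(x) x@temperature)

#' @describeIn ContactProfile-class temperature of the analysed trajectory.
#' @export
setMethod("temperature", "ContactProfile", function(x) x@temperature)

#' @describeIn BeadChain-class bead coordinate matrix (nm).
#' @export
setMethod("positions", "BeadChain", function(x) x@positions)

#' @describeIn BeadChain-class residue numbers.
#' @export
setMethod("residueIds", "BeadChain", function(x) x@residueIds)

#' @describeIn Trajectory-class residue numbers.
#' @export
setMethod("residueIds", "Trajectory", function(x) x@residueIds)

#' @describeIn ContactProfile-class residue numbers.
#' @export
setMethod("residueIds", "ContactProfile", function(x) x@residueIds)

#' @describeIn BeadChain-class conformational-state tag.
#' @export
setMethod("conformationalState", "BeadChain", function(x) x@state)

#' @describeIn ContactProfile-class per-residue contact indices, named by
#'   residue.
#' @param x a [ContactProfile-class].
#' @export
contactIndex <- function(x) {
  stopifnot(is(x, "ContactProfile"))
  setNames(x@index, x@residueIds)
}

#' @describeIn MeltingCurve-class curve points as a data.frame with columns
#'   `temperature` and `index`.
#' @param x a [MeltingCurve-class].
#' @export
meltingPoints <- function(x) {
  stopifnot(is(x, "MeltingCurve"))
  data.frame(temperature = x@temperature, index = x@index)
}

#' @describeIn PMFProfile-class free energy in kcal/mol.
#' @param x a [PMFProfile-class].
#' @export
freeEnergyKcal <- function(x) {
  stopifnot(is(x, "PMFProfile"))
  x@freeEnergy / .kJperKcal
}

setMethod("show", "RestraintParams", function(object) {
  cat(sprintf("RestraintParams [%s]\n", object@state))
  cat(sprintf("  angle:    K = %g kJ/mol, thetaMin = %g deg, sigma = %g deg^2\n",
              object@Kangle, object@thetaMin, object@sigmaAngle))
  cat(sprintf("  dihedral: K = %g kJ/mol, phiMin = %g deg, sigma = %g deg^2\n",
              object@Kdihedral, object@phiMin, object@sigmaDihedral))
})

setMethod("show", "BeadChain", function(object) {
  n <- nrow(object@positions)
  cat(sprintf("BeadChain: %d beads, residues %d-%d, state %s\n", n,
              min(object@residueIds), max(object@residueIds), object@state))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames, %d residues, %d phosphates, %g K\n",
              nFrames(object), nResidues(object), nrow(object@phosphates),
              object@temperature))
  cat(sprintf("  box %g x %g x %g nm (xy-periodic)\n",
              object@box[1], object@box[2], object@box[3]))
})

setMethod("show", "ContactProfile", function(object) {
  cat(sprintf("ContactProfile at %g K: %d residues, global index %.3f\n",
              object@temperature, length(object@index), mean(object@index)))
})

setMethod("show", "MeltingCurve", function(object) {
  cat(sprintf("MeltingCurve: %d temperatures, %g-%g K\n",
              length(object@temperature), min(object@temperature),
              max(object@temperature)))
  if (length(object@fit))
    cat(sprintf("  fitted Tm = %.1f K (width %.1f K)\n",
                object@fit$Tm, object@fit$width))
})

setMethod("show", "UmbrellaWindow", function(object) {
  cat(sprintf("UmbrellaWindow: center %.3f nm, k = %g kJ/mol/nm^2, %d samples\n",
              object@center, object@forceConstant, length(object@samples)))
})

setMethod("show", "PMFProfile", function(object) {
  ok <- is.finite(object@freeEnergy)
  cat(sprintf("PMFProfile: %d bins over %.3f-%.3f nm at %g K (%d occupied)\n",
              length(object@grid), min(object@grid), max(object@grid),
              object@temperature, sum(ok)))
  cat(sprintf("  reference: %s\n", object@reference))
})
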