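# Per-frame, per-residue contact indicators for a trajectory; minimum
# image in xy, plain distance in z, both leaflet planes included in the
# static phosphate set stored on the trajectory.
.contactMatrix <- function(traj, threshold = 1, burnIn = 0) {
  stopifnot(is(traj, "Trajectory"))
  validObject(traj)
  if (threshold <= 0) stop("threshold must be > 0 (nm)")
  if (burnIn < 0 || burnIn >= 1) stop("burnIn must be a fraction in [0, 1)")
  cm <- .contactMatrixCpp(traj@peptide, traj@phosphates,
                          traj@box[1], traj@box[2], threshold)
  if (burnIn > 0) {
    drop <- floor(nrow(cm) * burnIn)
    if (drop >= nrow(cm)) stop("burnIn leaves no frames")
    cm <- cm[(drop + 1):nrow(cm), , drop = FALSE]
  }
  colnames(cm) <- traj@residueIds
  cm
}

#' Contact index of one residue
#'
#' Fraction of frames in which the minimum distance between the residue's
#' backbone bead and any phosphate bead falls below the threshold (1 nm in
#' the study).  Distances use the minimum image in the periodic xy plane
#' and the plain distance in z.
#'
#' @param traj a [Trajectory-class].
#' @param residueId residue number.
#' @param threshold contact distance cutoff, nm.
#' @param burnIn fraction of initial frames to discard (default 0: the
#'   whole trajectory is analysed).
#' @return A fraction in \[0, 1\].
#' @export
residueContactIndex <- function(traj, residueId, threshold = 1, burnIn = 0) {
  idx <- match(residueId, traj@residueIds)
  if (is.na(idx))
    stop(sprintf("unknown residue %s; valid ids: %s", residueId,
                 paste(traj@residueIds, collapse = ", ")))
  mean(.contactMatrix(traj, threshold, burnIn)[, idx])
}

#' Per-residue contact profile of a trajectory
#'
#' @inheritParams residueContactIndex
#' @return A [ContactProfile-class] with one index per residue.
#' @seealso [globalContactIndex()], [meltingCurve()]
#' @export
contactProfile <- function(traj, threshold = 1, burnIn = 0) {
  cm <- .contactMatrix(traj, threshold, burnIn)
  if (nrow(cm) == 0) stop("empty trajectory")
  new("ContactProfile", temperature = traj@temperature,
      residueIds = traj@residueIds, index = colMeans(cm))
}

#' @describeIn globalContactIndex mean contact index over the residues of
#'   a profile.
#' @export
setMethod("globalContactIndex", "ContactProfile", function(x) {
  validObject(x)
  mean(x@index)
})

#' Melting curve from contact profiles across a temperature ladder
#'
#' Collects the global contact index of each profile and orders the points
#' by temperature.  Duplicate temperatures are rejected as an ambiguous
#' ladder.
#'
#' @param profiles list of [ContactProfile-class] objects at >= 2 distinct
#'   temperatures.
#' @return A [MeltingCurve-class] (unfitted).
#' @export
meltingCurve <- function(profiles) {
  stopifnot(length(profiles) >= 2, all(vapply(profiles, is, logical(1),
                                              "ContactProfile")))
  temps <- vapply(profiles, temperature, numeric(1))
  if (anyDuplicated(temps))
    stop("duplicate temperatures in the ladder: ",
         paste(unique(temps[duplicated(temps)]), collapse = ", "))
  gci <- vapply(profiles, globalContactIndex, numeric(1))
  o <- order(temps)
  new("MeltingCurve", temperature = temps[o], index = gci[o], fit = list())
}

#' Fit the melting temperature of a binding curve
#'
#' Least-squares fit of the four-parameter logistic
#' \deqn{c(T) = c_{low} + (c_{high} - c_{low}) / (1 + e^{(T - T_m)/w})}
#' by Levenberg-Marquardt; Tm is the inflection point, `width` the slope
#' parameter w (K).  If the curve spans less than 0.2 in global contact
#' index the fit is flagged low-confidence.
#'
#' @param curve a [MeltingCurve-class].
#' @return The curve with its `fit` slot filled: `Tm`, `width`, `cLow`,
#'   `cHigh`, `residual` (RMS), `lowConfidence`, and `TmSE` when
#'   available.  Retrieve via `meltingFit()`.
#' @examples
#' tl <- seq(310, 450, 10)
#' cv <- new("MeltingCurve", temperature = tl,
#'           index = 1 / (1 + exp((tl - 372) / 15)), fit = list())
#' meltingFit(fitMeltingTemperature(cv))$Tm
#' @export
fitMeltingTemperature <- function(curve) {
  stopifnot(is(curve, "MeltingCurve"))
  validObject(curve)
  Tv <- curve@temperature; cv <- curve@index
  lowConf <- (max(cv) - min(cv)) <= 0.2
  mid <- (max(cv) + min(cv)) / 2
  start <- list(cLow = min(cv), cHigh = max(cv),
                Tm = Tv[which.min(abs(cv - mid))], w = diff(range(Tv)) / 10)
  fit <- tryCatch(
    minpack.lm::nlsLM(cv ~ cLow + (cHigh - cLow) / (1 + exp((Tv - Tm) / w)),
                      start = start,
                      lower = c(cLow = 0, cHigh = 0,
                                Tm = min(Tv) - diff(range(Tv)),
                                w = 1e-3),
                      upper = c(cLow = 1, cHigh = 1,
                                Tm = max(Tv) + diff(range(Tv)), w = 500),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("melting fit did not converge: ", conditionMessage(e),
           "; curve range = ", signif(max(cv) - min(cv), 3)))
  par <- as.list(coef(fit))
  if (par$Tm < min(Tv) || par$Tm > max(Tv))
    warning(sprintf("fitted Tm = %.1f K lies outside the sampled ladder %g-%g K",
                    par$Tm, min(Tv), max(Tv)))
  se <- tryCatch(summary(fit)$coefficients["Tm", "Std. Error"],
                 error = function(e) NA_real_)
  curve@fit <- list(Tm = par$Tm, width = par$w, cLow = par$cLow,
                    cHigh = par$cHigh,
                    residual = sqrt(mean(residuals(fit)^2)),
                    TmSE = se, lowConfidence = lowConf)
  curve
}

#' @describeIn fitMeltingTemperature extract the fit list of a fitted
#'   curve (`NULL` if unfitted).
#' @param curve a [MeltingCurve-class].
#' @export
meltingFit <- function(curve) {
  stopifnot(is(curve, "MeltingCurve"))
  if (!length(curve@fit)) return(NULL)
  curve@fit
}

#' Three-segment convergence diagnostic
#'
#' Splits a trajectory into consecutive equal-length segments (remainder
#' frames dropped from the end), computes a contact profile per segment,
#' and reports the maximum absolute per-residue deviation between any two
#' segments.  The study used three segments per run.
#'
#' @param traj a [Trajectory-class].
#' @param nSegments number of segments (default 3).
#' @param threshold contact cutoff, nm.
#' @return List with `profiles` (one [ContactProfile-class] per segment),
#'   `segmentLength` (frames) and `maxDeviation`.
#' @export
segmentConvergence <- function(traj, nSegments = 3, threshold = 1) {
  stopifnot(is(traj, "Trajectory"))
  nf <- nFrames(traj)
  if (nSegments < 2) stop("nSegments must be >= 2")
  if (nf < nSegments)
    stop(sprintf("too few frames (%d) for %d segments", nf, nSegments))
  segLen <- nf %/% nSegments
  cm <- .contactMatrix(traj, threshold)
  profs <- lapply(seq_len(nSegments), function(s) {
    rows <- ((s - 1) * segLen + 1):(s * segLen)
    new("ContactProfile", temperature = traj@temperature,
        residueIds = traj@residueIds, index = colMeans(cm[rows, , drop = FALSE]))
  })
  mat <- do.call(rbind, lapply(profs, slot, "index"))
  dev <- 0
  for (a in seq_len(nSegments - 1))
    for (b in (a + 1):nSegments)
      dev <- max(dev, max(abs(mat[a, ] - mat[b, ])))
  list(profiles = profs, segmentLength = segLen, maxDeviation = dev)
}
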