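#' @rdname BilayerTrajectory-class
setMethod("nFrames", "BilayerTrajectory", function(x) dim(x@coords)[3])

#' @rdname BilayerTrajectory-class
setMethod("nAtoms", "BilayerTrajectory", function(x) dim(x@coords)[1])

#' @rdname BilayerTrajectory-class
setMethod("topology", "BilayerTrajectory", function(x) x@topology)

#' @rdname BilayerTrajectory-class
setMethod("frameCoords", "BilayerTrajectory", function(x, frame) {
  if (missing(frame)) return(x@coords)
  frame <- as.integer(frame)
  if (frame < 1L || frame > nFrames(x))
    stop("frame index out of range")
  m <- x@coords[, , frame, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  colnames(m) <- c("x", "y", "z")
  m
})

#' @rdname BilayerTrajectory-class
setMethod("frameTimes", "BilayerTrajectory", function(x) x@time)

#' @rdname BilayerTrajectory-class
setMethod("boxVectors", "BilayerTrajectory", function(x) x@box)

#' @rdname BilayerTrajectory-class
setMethod("groundTruth", "BilayerTrajectory", function(x)
  x@metadata$groundTruth)

setMethod("show", "BilayerTrajectory", function(object) {
  cat(sprintf("BilayerTrajectory: %d atoms, %d frames (%.3f-%.3f ns)\n",
              nAtoms(object), nFrames(object),
              min(object@time), max(object@time)))
  cat(sprintf("  residues: %s\n",
              paste(unique(object@topology$resname), collapse = ", ")))
  cat(sprintf("  box (frame 1): %.3f x %.3f x %.3f nm\n",
              object@box[1, 1], object@box[1, 2], object@box[1, 3]))
  if (!is.null(object@metadata$groundTruth))
    cat("  carries generator ground truth\n")
})

#' Extract a single frame as a one-frame trajectory
#'
#' @param x a \code{BilayerTrajectory}.
#' @param frame integer frame index.
#' @return a \code{BilayerTrajectory} with one frame.
#' @export
getFrame <- function(x, frame) {
  stopifnot(is(x, "BilayerTrajectory"))
  frame <- as.integer(frame)
  if (frame < 1L || frame > nFrames(x)) stop("frame index out of range")
  new("BilayerTrajectory",
      coords = x@coords[, , frame, drop = FALSE],
      topology = x@topology,
      box = x@box[frame, , drop = FALSE],
      time = x@time[frame],
      metadata = x@metadata)
}

#' @rdname ExcitationSet-class
setMethod("records", "ExcitationSet", function(x) x@records)

#' @rdname ExcitationSet-class
setMethod("excitationKind", "ExcitationSet", function(x) x@kind)

setMethod("show", "ExcitationSet", function(object) {
  r <- object@records
  cat(sprintf("ExcitationSet (%s): %d records, %d snapshots, states %s\n",
              object@kind, nrow(r), length(unique(r$snapshot)),
              paste(range(r$state), collapse = "-")))
  cat(sprintf("  energy: %.3f-%.3f eV; <f> = %.3f\n",
              min(r$energy_eV), max(r$energy_eV), mean(r$osc_strength)))
  if (all(c("depth_nm", "tilt_deg") %in% names(r)))
    cat("  annotated with depth/tilt descriptors\n")
})

#' @rdname EnsembleManifest-class
setMethod("manifestEntries", "EnsembleManifest", function(x) x@entries)

setMethod("show", "EnsembleManifest", function(object) {
  cat(sprintf("EnsembleManifest [%s]: %d entries from %d trajectories\n",
              object@stage, nrow(object@entries),
              length(unique(object@entries$trajectory))))
})

#' @rdname ChargeEnvironment-class
setMethod("totalCharge", "ChargeEnvironment", function(x) sum(x@charges))

setMethod("show", "ChargeEnvironment", function(object) {
  cat(sprintf(
    "ChargeEnvironment: %d point charges, %d molecules, total %+.6f e (%s)\n",
    length(object@charges), length(unique(object@molids)),
    sum(object@charges), object@units))
})

#' @rdname OrientationHistogram-class
setMethod("binCenters", "OrientationHistogram", function(x)
  (x@edges[-1] + x@edges[-length(x@edges)]) / 2)

#' @rdname OrientationHistogram-class
setMethod("binDensity", "OrientationHistogram", function(x) x@density)

setMethod("show", "OrientationHistogram", function(object) {
  cat(sprintf(
    "OrientationHistogram: %d bins of width %.4g on [%.4g, %.4g], n = %d\n",
    length(object@density), object@binWidth, min(object@edges),
    max(object@edges), object@nSamples))
  cat(sprintf("  mode at %.4g\n", histogramMode(object)))
})

setMethod("show", "SpectrumGrid", function(object) {
  cat(sprintf(
    "SpectrumGrid (%s axis): %d points on [%.4g, %.4g], FWHM %.3g eV, %d snapshots\n",
    object@unit, length(object@axis), min(object@axis), max(object@axis),
    object@delta, object@nSnapshots))
})

setMethod("show", "AssociationResult", function(object) {
  cat(sprintf(
    "AssociationResult: deep (> %.3g nm) & low-tilt (< %.3g deg) group of %d vs %d\n",
    object@depthThresh, object@tiltThresh,
    object@groupSizes[1], object@groupSizes[2]))
  cat(sprintf("  mean energy difference: %+.4f eV; permutation p = %.4g (%d perms)\n",
              object@statistic, object@pValue, object@nPerm))
})

setMethod("show", "QMFragment", function(object) {
  cat(sprintf("QMFragment: %d atoms, net charge %+d, %d link hydrogen(s)\n",
              nrow(object@atoms), as.integer(round(object@netCharge)),
              nrow(object@linkAtoms)))
})

setMethod("show", "SamplingPlan", function(object) {
  cat(sprintf("SamplingPlan: %d %s snapshots on [%.4g, %.4g] ns\n",
              object@n, object@mode, object@window[1], object@window[2]))
})

setMethod("show", "TrajectoryParams", function(object) {
  modes <- vapply(object@tiltModel, function(cmp) cmp$modeDeg, numeric(1))
  cat(sprintf(
    "TrajectoryParams: %d frames @ %.4g ns, tilt mode(s) %s deg, depth N(%.3g, %.3g) nm\n",
    object@nFrames, object@frameInterval,
    paste(format(modes), collapse = "/"),
    object@depthModel$meanNm, object@depthModel$sdNm))
})

setMethod("show", "CouplingParams", function(object) {
  cat(sprintf(
    "CouplingParams: E = %.3g %+.3g*depth %+.3g*cos(tilt) + N(0, %.3g) eV\n",
    object@baseEnergy, object@depthSlope, object@tiltSlope, object@noiseSd))
})
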