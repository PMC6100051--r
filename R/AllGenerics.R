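#' @rdname BilayerTrajectory-class
#' @param x a \code{BilayerTrajectory}.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname BilayerTrajectory-class
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname BilayerTrajectory-class
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' @rdname BilayerTrajectory-class
#' @param frame integer frame index, or missing for all frames.
#' @export
setGeneric("frameCoords", function(x, frame) standardGeneric("frameCoords"))

#' @rdname BilayerTrajectory-class
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname BilayerTrajectory-class
#' @export
setGeneric("boxVectors", function(x) standardGeneric("boxVectors"))

#' @rdname BilayerTrajectory-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname ExcitationSet-class
#' @param x an \code{ExcitationSet}.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname ExcitationSet-class
#' @export
setGeneric("excitationKind", function(x) standardGeneric("excitationKind"))

#' @rdname EnsembleManifest-class
#' @param x an \code{EnsembleManifest}.
#' @export
setGeneric("manifestEntries", function(x) standardGeneric("manifestEntries"))

#' @rdname ChargeEnvironment-class
#' @param x a \code{ChargeEnvironment}.
#' @export
setGeneric("totalCharge", function(x) standardGeneric("totalCharge"))

#' @rdname OrientationHistogram-class
#' @param x an \code{OrientationHistogram}.
#' @export
setGeneric("histogramMode", function(x) standardGeneric("histogramMode"))

#' @rdname OrientationHistogram-class
#' @param ... method-specific arguments.
#' @export
setGeneric("localModes", function(x, ...) standardGeneric("localModes"))

#' @rdname OrientationHistogram-class
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' @rdname OrientationHistogram-class
#' @export
setGeneric("binDensity", function(x) standardGeneric("binDensity"))
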