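#' @import methods
NULL

.topologyColumns <- c("name", "element", "resid", "resname", "molid",
                      "mass", "charge")

#' Multi-frame bilayer + probe trajectory
#'
#' Container for a sequence of coordinate frames of a probe embedded in a
#' planar lipid bilayer, together with the topology needed by the geometric
#' observables (atom names, masses, per-atom partial charges, molecule
#' membership) and per-frame orthorhombic box vectors.
#'
#' Coordinates are stored in an \code{nAtoms x 3 x nFrames} array in
#' nanometres; the membrane normal is the laboratory z axis. The
#' \code{metadata} list carries provenance such as the generator ground truth
#' for synthetic trajectories (element \code{groundTruth}).
#'
#' @slot coords numeric array, \code{nAtoms x 3 x nFrames}, nm.
#' @slot topology data.frame with columns \code{name}, \code{element},
#'   \code{resid}, \code{resname}, \code{molid}, \code{mass}, \code{charge}.
#' @slot box numeric matrix, \code{nFrames x 3}, orthorhombic box edges in nm.
#' @slot time numeric vector of frame times in ns.
#' @slot metadata list of provenance entries.
#'
#' @exportClass BilayerTrajectory
setClass("BilayerTrajectory",
         representation(coords = "array",
                        topology = "data.frame",
                        box = "matrix",
                        time = "numeric",
                        metadata = "list"))

setValidity("BilayerTrajectory", function(object) {
  msg <- character()
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    msg <- c(msg, "'coords' must be an nAtoms x 3 x nFrames array")
  else {
    if (nrow(object@topology) != d[1])
      msg <- c(msg, "topology rows must match number of atoms")
    if (nrow(object@box) != d[3])
      msg <- c(msg, "box rows must match number of frames")
    if (length(object@time) != d[3])
      msg <- c(msg, "time length must match number of frames")
  }
  if (!all(.topologyColumns %in% names(object@topology)))
    msg <- c(msg, paste("topology must contain columns:",
                        paste(.topologyColumns, collapse = ", ")))
  if (!all(is.finite(object@coords)))
    msg <- c(msg, "all coordinates must be finite")
  if (ncol(object@box) != 3L || !all(is.finite(object@box)) ||
      any(object@box <= 0))
    msg <- c(msg, "box edges must be positive and finite")
  if (length(msg)) msg else TRUE
})

#' Parameters of the synthetic bilayer trajectory generator
#'
#' Defines the study conditions a synthetic trajectory emulates: a mixture
#' model for the fluorophore tilt angle (angular kernels on [0, 180] degrees),
#' a Gaussian model for penetration depth, the bilayer dimensions and
#' phosphate-plane positions, and the random seed.
#'
#' @slot nFrames integer, number of frames (>= 1).
#' @slot frameInterval numeric, time between frames in ns.
#' @slot nLipidsPerLeaflet integer, phosphate pseudo-atoms per leaflet.
#' @slot box numeric length-3, box edges in nm.
#' @slot tiltModel list of components \code{list(modeDeg, concentration,
#'   weight)}; weights must sum to 1, concentrations must be positive
#'   (\code{Inf} gives a point mass at the mode).
#' @slot depthModel list \code{list(meanNm, sdNm)}, Gaussian penetration
#'   depth; \code{sdNm >= 0}.
#' @slot phosphatePlaneZ numeric length-2, z of the lower and upper leaflet
#'   phosphate planes in nm.
#' @slot leaflet character, leaflet hosting the probe ("upper" or "lower").
#' @slot seed integer random seed.
#'
#' @exportClass TrajectoryParams
setClass("TrajectoryParams",
         representation(nFrames = "integer",
                        frameInterval = "numeric",
                        nLipidsPerLeaflet = "integer",
                        box = "numeric",
                        tiltModel = "list",
                        depthModel = "list",
                        phosphatePlaneZ = "numeric",
                        leaflet = "character",
                        seed = "integer"))

setValidity("TrajectoryParams", function(object) {
  msg <- character()
  if (object@nFrames < 1L) msg <- c(msg, "nFrames must be >= 1")
  if (object@nLipidsPerLeaflet < 1L)
    msg <- c(msg, "nLipidsPerLeaflet must be >= 1")
  if (length(object@box) != 3L || any(object@box <= 0))
    msg <- c(msg, "box must be three positive edge lengths (nm)")
  w <- vapply(object@tiltModel, function(cmp) cmp$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-9)
    msg <- c(msg, "tilt mixture weights must sum to 1")
  kap <- vapply(object@tiltModel, function(cmp) cmp$concentration, numeric(1))
  if (any(kap <= 0)) msg <- c(msg, "tilt concentrations must be > 0")
  modes <- vapply(object@tiltModel, function(cmp) cmp$modeDeg, numeric(1))
  if (any(modes < 0 | modes > 180))
    msg <- c(msg, "tilt modes must lie in [0, 180] degrees")
  if (object@depthModel$sdNm < 0) msg <- c(msg, "depth sdNm must be >= 0")
  if (length(object@phosphatePlaneZ) != 2L ||
      object@phosphatePlaneZ[1] >= object@phosphatePlaneZ[2])
    msg <- c(msg, "phosphatePlaneZ must be c(lower, upper) with lower < upper")
  if (!object@leaflet %in% c("upper", "lower"))
    msg <- c(msg, "leaflet must be 'upper' or 'lower'")
  if (length(msg)) msg else TRUE
})

#' Parameters of the synthetic geometry-to-energy coupling
#'
#' Linear coupling of emission energy to penetration depth and the cosine of
#' the tilt angle, plus Gaussian noise; oscillator strengths are Gaussian
#' truncated at zero.
#'
#' @slot baseEnergy numeric, eV.
#' @slot depthSlope numeric, eV per nm of penetration depth.
#' @slot tiltSlope numeric, eV per unit of cos(tilt).
#' @slot noiseSd numeric, eV, standard deviation of the energy noise (>= 0).
#' @slot fMean numeric, mean oscillator strength (> 0).
#' @slot fSd numeric, oscillator strength standard deviation (>= 0).
#' @slot seed integer random seed.
#'
#' @exportClass CouplingParams
setClass("CouplingParams",
         representation(baseEnergy = "numeric",
                        depthSlope = "numeric",
                        tiltSlope = "numeric",
                        noiseSd = "numeric",
                        fMean = "numeric",
                        fSd = "numeric",
                        seed = "integer"))

setValidity("CouplingParams", function(object) {
  msg <- character()
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@fMean <= 0) msg <- c(msg, "fMean must be > 0")
  if (object@fSd < 0) msg <- c(msg, "fSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Normalised binned distribution of a geometric observable
#'
#' Density-normalised histogram of tilt angles (degrees) or penetration
#' depths (nm): the bin densities integrate to one.
#'
#' @slot edges numeric, bin edges (length nBins + 1), strictly increasing.
#' @slot density numeric, per-bin density (>= 0).
#' @slot nSamples integer, number of samples binned.
#' @slot binWidth numeric, common bin width.
#'
#' @exportClass OrientationHistogram
setClass("OrientationHistogram",
         representation(edges = "numeric",
                        density = "numeric",
                        nSamples = "integer",
                        binWidth = "numeric"))

setValidity("OrientationHistogram", function(object) {
  msg <- character()
  if (length(object@edges) != length(object@density) + 1L)
    msg <- c(msg, "edges must have length(density) + 1 entries")
  if (any(diff(object@edges) <= 0))
    msg <- c(msg, "edges must be strictly increasing")
  if (any(object@density < 0)) msg <- c(msg, "densities must be >= 0")
  tot <- sum(object@density * diff(object@edges))
  if (object@nSamples > 0L && abs(tot - 1) > 1e-9)
    msg <- c(msg, "densities must integrate to 1")
  if (length(msg)) msg else TRUE
})

#' Snapshot-selection plan
#'
#' A window of trajectory time, a snapshot count, and the selection mode
#' (equidistant with both endpoints included, or uniform random without
#' replacement).
#'
#' @slot window numeric length-2, \code{c(tStart, tEnd)} in ns.
#' @slot n integer, number of snapshots (>= 1).
#' @slot mode character, "equidistant" or "random".
#' @slot seed integer, used in random mode.
#'
#' @exportClass SamplingPlan
setClass("SamplingPlan",
         representation(window = "numeric",
                        n = "integer",
                        mode = "character",
                        seed = "integer"))

setValidity("SamplingPlan", function(object) {
  msg <- character()
  if (length(object@window) != 2L || object@window[1] >= object@window[2])
    msg <- c(msg, "window must be c(tStart, tEnd) with tStart < tEnd")
  if (object@n < 1L) msg <- c(msg, "n must be >= 1")
  if (!object@mode %in% c("equidistant", "random"))
    msg <- c(msg, "mode must be 'equidistant' or 'random'")
  if (length(msg)) msg else TRUE
})

#' Manifest of selected snapshots
#'
#' Book-keeping of which frames of which trajectory enter an excitation
#' ensemble, with the protocol stage they belong to.
#'
#' @slot entries data.frame with columns \code{stage}, \code{trajectory},
#'   \code{frame}, \code{time_ns} (frame is NA for entries referring to
#'   secondary trajectories that are not materialised).
#' @slot stage character, protocol stage label.
#'
#' @exportClass EnsembleManifest
setClass("EnsembleManifest",
         representation(entries = "data.frame",
                        stage = "character"))

setValidity("EnsembleManifest", function(object) {
  msg <- character()
  need <- c("stage", "trajectory", "frame", "time_ns")
  if (!all(need %in% names(object@entries)))
    msg <- c(msg, paste("entries must contain columns:",
                        paste(need, collapse = ", ")))
  else {
    key <- paste(object@entries$trajectory, object@entries$time_ns)
    if (anyDuplicated(key))
      msg <- c(msg, "entries must be unique by (trajectory, time)")
  }
  if (length(msg)) msg else TRUE
})

#' Set of vertical electronic transitions
#'
#' One record per vertical transition: snapshot id, excited-state index,
#' transition energy (eV) and oscillator strength, optionally annotated with
#' the geometric descriptors (penetration depth, tilt angle) of the snapshot.
#'
#' @slot records data.frame with columns \code{snapshot}, \code{state},
#'   \code{energy_eV}, \code{osc_strength} and optionally \code{depth_nm},
#'   \code{tilt_deg}.
#' @slot kind character, "absorption" or "emission".
#'
#' @exportClass ExcitationSet
setClass("ExcitationSet",
         representation(records = "data.frame",
                        kind = "character"))

setValidity("ExcitationSet", function(object) {
  msg <- character()
  need <- c("snapshot", "state", "energy_eV", "osc_strength")
  if (!all(need %in% names(object@records)))
    msg <- c(msg, paste("records must contain columns:",
                        paste(need, collapse = ", ")))
  else {
    if (any(object@records$energy_eV <= 0))
      msg <- c(msg, "transition energies must be > 0 eV")
    if (any(object@records$osc_strength < 0))
      msg <- c(msg, "oscillator strengths must be >= 0")
    if (any(object@records$state < 1))
      msg <- c(msg, "state indices must be >= 1")
  }
  if (!object@kind %in% c("absorption", "emission"))
    msg <- c(msg, "kind must be 'absorption' or 'emission'")
  if (length(msg)) msg else TRUE
})

#' Point-charge environment around a quantum fragment
#'
#' Fixed point charges representing water and lipids around the
#' quantum-mechanical probe fragment in an electrostatic-embedding
#' calculation. Molecules are always included whole so the total charge is
#' the sum of the included molecules' formal charges.
#'
#' @slot positions numeric matrix, n x 3, in the units given by \code{units}.
#' @slot charges numeric, elementary charges.
#' @slot molids integer, source molecule id per point.
#' @slot units character, "nm" or "bohr".
#'
#' @exportClass ChargeEnvironment
setClass("ChargeEnvironment",
         representation(positions = "matrix",
                        charges = "numeric",
                        molids = "integer",
                        units = "character"))

setValidity("ChargeEnvironment", function(object) {
  msg <- character()
  if (nrow(object@positions) != length(object@charges) ||
      length(object@charges) != length(object@molids))
    msg <- c(msg, "positions, charges and molids must agree in length")
  if (ncol(object@positions) != 3L)
    msg <- c(msg, "positions must have three columns")
  if (!object@units %in% c("nm", "bohr"))
    msg <- c(msg, "units must be 'nm' or 'bohr'")
  if (length(msg)) msg else TRUE
})

#' Quantum fragment obtained by alkyl-chain truncation
#'
#' The fluorophore moiety kept in the quantum region after replacing the
#' alkyl tail with a methyl group, including the link-hydrogen record for the
#' cut bond.
#'
#' @slot atoms data.frame with columns \code{name}, \code{element}.
#' @slot positions numeric matrix, n x 3, nm.
#' @slot netCharge numeric, integer-valued net charge of the fragment.
#' @slot linkAtoms data.frame with one row per truncated bond: columns
#'   \code{kept}, \code{removed}, \code{hx}, \code{hy}, \code{hz}.
#'
#' @exportClass QMFragment
setClass("QMFragment",
         representation(atoms = "data.frame",
                        positions = "matrix",
                        netCharge = "numeric",
                        linkAtoms = "data.frame"))

setValidity("QMFragment", function(object) {
  msg <- character()
  if (nrow(object@atoms) != nrow(object@positions))
    msg <- c(msg, "atoms and positions must agree in length")
  if (abs(object@netCharge - round(object@netCharge)) > 1e-6)
    msg <- c(msg, "net charge must be integer-valued")
  if (length(msg)) msg else TRUE
})

#' Intensity versus energy (or wavelength) spectrum
#'
#' A nuclear-ensemble spectrum: oscillator-strength-weighted sum of broadened
#' lines over snapshots, divided by the number of distinct snapshots.
#'
#' @slot axis numeric, strictly monotone energy (eV) or wavelength (nm) grid.
#' @slot intensity numeric, non-negative intensities (arbitrary units).
#' @slot unit character, "eV" or "nm".
#' @slot delta numeric, Lorentzian full width at half maximum in eV.
#' @slot kernel character, broadening kernel name.
#' @slot nSnapshots integer, number of distinct snapshots averaged.
#'
#' @exportClass SpectrumGrid
setClass("SpectrumGrid",
         representation(axis = "numeric",
                        intensity = "numeric",
                        unit = "character",
                        delta = "numeric",
                        kernel = "character",
                        nSnapshots = "integer"))

setValidity("SpectrumGrid", function(object) {
  msg <- character()
  if (length(object@axis) != length(object@intensity))
    msg <- c(msg, "axis and intensity must agree in length")
  dd <- diff(object@axis)
  if (!(all(dd > 0) || all(dd < 0)))
    msg <- c(msg, "axis must be strictly monotone")
  if (any(object@intensity < -1e-12))
    msg <- c(msg, "intensities must be >= 0")
  if (!object@unit %in% c("eV", "nm"))
    msg <- c(msg, "unit must be 'eV' or 'nm'")
  if (length(msg)) msg else TRUE
})

#' Result of the geometry/emission-energy association test
#'
#' Difference in mean emission energy between the deep, weakly tilted
#' subgroup and the rest of the ensemble, with a two-sided permutation
#' p-value.
#'
#' @slot statistic numeric, mean energy difference in eV (group minus rest).
#' @slot pValue numeric in [0, 1].
#' @slot depthThresh numeric, nm; the deep group has depth > depthThresh.
#' @slot tiltThresh numeric, degrees; the group has tilt < tiltThresh.
#' @slot groupSizes integer length-2, c(group, rest).
#' @slot nPerm integer, number of label permutations.
#' @slot seed integer, permutation seed.
#'
#' @exportClass AssociationResult
setClass("AssociationResult",
         representation(statistic = "numeric",
                        pValue = "numeric",
                        depthThresh = "numeric",
                        tiltThresh = "numeric",
                        groupSizes = "integer",
                        nPerm = "integer",
                        seed = "integer"))

setValidity("AssociationResult", function(object) {
  msg <- character()
  if (object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (length(object@groupSizes) != 2L || any(object@groupSizes < 0))
    msg <- c(msg, "groupSizes must be two non-negative counts")
  if (length(msg)) msg else TRUE
})
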