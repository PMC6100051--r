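#' Build a trajectory object from coordinates and topology
#'
#' Low-level constructor used by readers, the synthetic generator, and
#' tests that assemble frames by hand.
#'
#' @param coords numeric array \code{nAtoms x 3 x nFrames} (a single
#'   \code{nAtoms x 3} matrix is promoted to one frame), nm.
#' @param topology topology data.frame (see \code{\link{readTopology}}).
#' @param box box edge lengths: length-3 vector or \code{nFrames x 3}
#'   matrix, nm.
#' @param time frame times in ns (default \code{0, 1, ...}).
#' @param metadata optional list of provenance entries.
#' @return a validated \code{BilayerTrajectory}.
#' @export
bilayerTrajectory <- function(coords, topology, box, time = NULL,
                              metadata = list()) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  nf <- dim(coords)[3]
  if (is.null(dim(box))) box <- matrix(rep(box, each = nf), nf, 3)
  if (is.null(time)) time <- seq_len(nf) - 1
  new("BilayerTrajectory", coords = coords, topology = topology,
      box = box, time = as.numeric(time), metadata = metadata)
}

# Resolve an atom selection (indices, or atom names matched against the
# topology) to integer indices.
.resolveSelection <- function(topology, sel) {
  if (is.numeric(sel)) {
    idx <- as.integer(sel)
    if (any(idx < 1L | idx > nrow(topology)))
      stop("selection index out of range")
    return(idx)
  }
  idx <- which(topology$name %in% sel)
  if (!length(idx))
    stop("selection error: no atoms named ", paste(sel, collapse = ", "))
  idx
}

.resolveSingleAtom <- function(topology, name) {
  idx <- which(topology$name == name)
  if (length(idx) == 0L)
    stop("selection error: atom '", name, "' not found")
  if (length(idx) > 1L)
    stop("selection error: atom '", name, "' matches ", length(idx),
         " atoms; expected exactly one")
  idx
}

#' Make a set of atoms whole across periodic boundaries
#'
#' Shifts each atom by box multiples so that all atoms lie in the same
#' periodic image as the first atom of the set. Required before any
#' centre-of-mass computation on wrapped coordinates.
#'
#' @param pos \code{n x 3} coordinate matrix, nm.
#' @param box length-3 box edges, nm.
#' @return the unwrapped coordinate matrix.
#' @export
makeWhole <- function(pos, box) {
  ref <- pos[1, ]
  d <- sweep(pos, 2, ref)
  d <- d - sweep(round(sweep(d, 2, box, `/`)), 2, box, `*`)
  sweep(d, 2, ref, `+`)
}

.phosphateIndices <- function(topology, phosphateName = "P") {
  idx <- which(topology$name == phosphateName |
                 toupper(topology$element) == "P")
  if (!length(idx)) stop("no phosphate atoms found in topology")
  idx
}

# Mass-weighted COM of a selection in one frame, with the selection made
# whole across periodic boundaries first.
.selectionCOM <- function(x, frame, idx) {
  pos <- frameCoords(x, frame)[idx, , drop = FALSE]
  pos <- makeWhole(pos, x@box[frame, ])
  .com(pos, x@topology$mass[idx])
}

#' Assign the probe to a bilayer leaflet
#'
#' The probe belongs to the upper leaflet when its centre of mass lies above
#' the bilayer midplane (the mean z of all phosphate atoms), to the lower
#' one when below; a probe exactly at the midplane is ambiguous and raises
#' an error.
#'
#' @param x a \code{BilayerTrajectory}.
#' @param frame frame index.
#' @param probeSelection atom names or indices of the probe (default: the
#'   fluorophore moiety atoms, falling back to the first molecule).
#' @param phosphateName atom name of the phosphate pseudo-atoms.
#' @return "upper" or "lower".
#' @export
assignLeaflet <- function(x, frame = 1L, probeSelection = NULL,
                          phosphateName = "P") {
  top <- x@topology
  idx <- .defaultProbeSelection(top, probeSelection)
  phos <- .phosphateIndices(top, phosphateName)
  pz <- frameCoords(x, frame)[phos, 3]
  mid <- mean(pz)
  comZ <- .selectionCOM(x, frame, idx)[3]
  if (abs(comZ - mid) < 1e-12)
    stop("ambiguous leaflet: probe centre of mass lies exactly at the midplane")
  if (comZ > mid) "upper" else "lower"
}

.defaultProbeSelection <- function(topology, probeSelection) {
  if (!is.null(probeSelection))
    return(.resolveSelection(topology, probeSelection))
  if (all(.fluorophoreAtoms %in% topology$name))
    return(match(.fluorophoreAtoms, topology$name))
  which(topology$molid == topology$molid[1])
}

#' Leaflet-oriented bilayer normal
#'
#' For planar bilayer trajectories the membrane normal is the laboratory z
#' axis. The returned vector is oriented per leaflet so that it always
#' points toward the water phase of the probe's leaflet: \code{(0, 0, 1)}
#' for the upper leaflet and \code{(0, 0, -1)} for the lower one. With this
#' convention a zero tilt always means "nitrogen toward water" regardless of
#' which leaflet hosts the probe.
#'
#' @param x a \code{BilayerTrajectory} (unused beyond validation: the
#'   normal is the fixed laboratory axis).
#' @param leaflet "upper" (default) or "lower".
#' @return unit 3-vector.
#' @export
bilayerNormal <- function(x = NULL, leaflet = "upper") {
  if (!leaflet %in% c("upper", "lower"))
    stop("leaflet must be 'upper' or 'lower'")
  if (leaflet == "upper") c(0, 0, 1) else c(0, 0, -1)
}

#' Fluorophore tilt angle
#'
#' Angle, in degrees, between the vector from the carbonyl carbon to the
#' nitrogen of the fluorophore moiety and the leaflet-oriented bilayer
#' normal. Zero degrees is a fluorophore parallel to the normal with the
#' nitrogen toward the water phase, 90 degrees perpendicular to the normal,
#' and 180 degrees a fluorophore pointing its nitrogen toward the membrane
#' interior.
#'
#' @param x a \code{BilayerTrajectory}.
#' @param frame frame index.
#' @param carbonyl atom name of the carbonyl carbon (exactly one match).
#' @param nitrogen atom name of the nitrogen (exactly one match).
#' @param leaflet "upper", "lower", or NULL to assign from the probe
#'   position.
#' @return tilt angle in degrees, in [0, 180].
#' @export
probeTiltAngle <- function(x, frame = 1L, carbonyl = "C1", nitrogen = "N1",
                           leaflet = NULL) {
  top <- x@topology
  iC <- .resolveSingleAtom(top, carbonyl)
  iN <- .resolveSingleAtom(top, nitrogen)
  if (is.null(leaflet))
    leaflet <- assignLeaflet(x, frame,
                             probeSelection = .defaultProbeSelection(top, NULL))
  pos <- frameCoords(x, frame)
  pair <- makeWhole(pos[c(iC, iN), , drop = FALSE], x@box[frame, ])
  v <- pair[2, ] - pair[1, ]
  if (sum(v * v) == 0) stop("carbonyl and nitrogen coincide")
  .vecAngleDeg(v, bilayerNormal(x, leaflet))
}

#' Penetration depth of the probe
#'
#' Signed distance along the leaflet-oriented bilayer normal between the
#' centre of mass of the host leaflet's phosphate atoms and the probe's
#' centre of mass. Positive values mean the probe lies deeper than the
#' phosphate plane (displaced toward the bilayer midplane); negative values
#' mean it protrudes toward the water phase.
#'
#' By default the probe centre of mass is that of the fluorophore moiety;
#' set \code{wholeMolecule = TRUE} to use the complete probe molecule
#' including its alkyl tail.
#'
#' @param x a \code{BilayerTrajectory}.
#' @param frame frame index.
#' @param probeSelection atom names or indices of the probe (default:
#'   fluorophore moiety).
#' @param wholeMolecule use the whole probe molecule instead of the
#'   fluorophore moiety.
#' @param phosphateName atom name of the phosphate pseudo-atoms.
#' @return signed depth in nm.
#' @export
penetrationDepth <- function(x, frame = 1L, probeSelection = NULL,
                             wholeMolecule = FALSE, phosphateName = "P") {
  top <- x@topology
  idx <- if (wholeMolecule && is.null(probeSelection))
    which(top$molid == top$molid[1])
  else .defaultProbeSelection(top, probeSelection)
  if (!length(idx)) stop("empty probe selection")
  leaflet <- assignLeaflet(x, frame, probeSelection = idx,
                           phosphateName = phosphateName)
  phos <- .phosphateIndices(top, phosphateName)
  pz <- frameCoords(x, frame)[phos, 3]
  mid <- mean(pz)
  hostPhos <- if (leaflet == "upper") phos[pz > mid] else phos[pz < mid]
  if (!length(hostPhos)) stop("no phosphate atoms in the host leaflet")
  phosCOM <- .selectionCOM(x, frame, hostPhos)
  probeCOM <- .selectionCOM(x, frame, idx)
  sum((phosCOM - probeCOM) * bilayerNormal(x, leaflet))
}

#' Acyl-chain tilt angle
#'
#' Angle between the vector from the first to the last atom of an acyl
#' chain and the leaflet-oriented normal, folded to [0, 90] degrees: zero
#' means a chain parallel to the normal (pointing toward the bilayer
#' midplane), 90 a chain lying in the membrane plane.
#'
#' @param x a \code{BilayerTrajectory}.
#' @param frame frame index.
#' @param chainSelection atom names or indices of the chain carbons, in
#'   chain order; at least two atoms.
#' @return folded tilt angle in degrees, in [0, 90].
#' @export
chainTiltAngle <- function(x, frame = 1L, chainSelection) {
  idx <- .resolveSelection(x@topology, chainSelection)
  if (length(idx) < 2L)
    stop("selection error: chain needs at least two atoms")
  pos <- makeWhole(frameCoords(x, frame)[idx, , drop = FALSE],
                   x@box[frame, ])
  v <- pos[nrow(pos), ] - pos[1, ]
  ang <- .vecAngleDeg(v, c(0, 0, 1))
  if (ang > 90) ang <- 180 - ang
  ang
}

#' Per-frame geometric observables of a trajectory
#'
#' Computes the fluorophore tilt angle and penetration depth for every
#' frame.
#'
#' @param x a \code{BilayerTrajectory}.
#' @param carbonyl,nitrogen atom names defining the tilt vector.
#' @param probeSelection probe selection for the depth (default:
#'   fluorophore moiety).
#' @param wholeMolecule use the whole probe molecule for the depth COM.
#' @return data.frame with columns \code{frame}, \code{time_ns},
#'   \code{tilt_deg}, \code{depth_nm}.
#' @export
analyzeGeometry <- function(x, carbonyl = "C1", nitrogen = "N1",
                            probeSelection = NULL, wholeMolecule = FALSE) {
  nf <- nFrames(x)
  tilt <- depth <- numeric(nf)
  for (f in seq_len(nf)) {
    tilt[f] <- probeTiltAngle(x, f, carbonyl, nitrogen)
    depth[f] <- penetrationDepth(x, f, probeSelection = probeSelection,
                                 wholeMolecule = wholeMolecule)
  }
  data.frame(frame = seq_len(nf), time_ns = frameTimes(x),
             tilt_deg = tilt, depth_nm = depth)
}
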