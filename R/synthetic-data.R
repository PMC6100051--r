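#' Construct synthetic-trajectory generator parameters
#'
#' The generator emulates a single solvatochromic probe embedded in one
#' leaflet of a planar bilayer of 64 lipids per leaflet: the fluorophore tilt
#' angle is drawn from a mixture of von Mises-type angular kernels on
#' [0, 180] degrees (unimodal near 28 degrees for a gel-like membrane,
#' bimodal with a second mode above 90 degrees for a fluid-like one) and the
#' penetration depth from a Gaussian. The probe is rigid; only its
#' orientation and position vary between frames. Lipids are represented by
#' static phosphate pseudo-atoms on the two phosphate planes.
#'
#' @param nFrames number of frames.
#' @param frameInterval time between frames, ns.
#' @param nLipidsPerLeaflet phosphate pseudo-atoms per leaflet.
#' @param box box edge lengths, nm.
#' @param tiltModel list of mixture components, each
#'   \code{list(modeDeg, concentration, weight)}; \code{concentration = Inf}
#'   collapses the component to a point mass.
#' @param depthModel \code{list(meanNm, sdNm)} Gaussian penetration depth.
#' @param phosphatePlaneZ z positions (nm) of the lower and upper phosphate
#'   planes.
#' @param leaflet leaflet hosting the probe, "upper" or "lower".
#' @param seed integer random seed.
#' @return a validated \code{TrajectoryParams} object.
#' @export
trajectoryParams <- function(nFrames = 1000L,
                             frameInterval = 0.1,
                             nLipidsPerLeaflet = 64L,
                             box = c(6.4, 6.4, 7.0),
                             tiltModel = list(
                               list(modeDeg = 28, concentration = 12,
                                    weight = 1)),
                             depthModel = list(meanNm = 0.8, sdNm = 0.15),
                             phosphatePlaneZ = c(1.6, 5.6),
                             leaflet = "upper",
                             seed = 1L) {
  new("TrajectoryParams",
      nFrames = as.integer(nFrames), frameInterval = frameInterval,
      nLipidsPerLeaflet = as.integer(nLipidsPerLeaflet),
      box = as.numeric(box), tiltModel = tiltModel,
      depthModel = depthModel,
      phosphatePlaneZ = as.numeric(phosphatePlaneZ),
      leaflet = leaflet, seed = as.integer(seed))
}

#' Construct geometry-to-energy coupling parameters
#'
#' Emission energies are linearly coupled to the penetration depth and to
#' cos(tilt): deeper and less tilted snapshots are shifted toward lower
#' energy (longer wavelength) by the default negative slopes, emulating the
#' association seen between probe embedding and emission colour.
#'
#' @param baseEnergy intercept energy, eV.
#' @param depthSlope eV per nm of depth.
#' @param tiltSlope eV per unit of cos(tilt).
#' @param noiseSd Gaussian energy noise, eV.
#' @param fMean mean oscillator strength.
#' @param fSd oscillator strength standard deviation (draws are truncated
#'   at zero).
#' @param seed integer random seed.
#' @return a validated \code{CouplingParams} object.
#' @export
couplingParams <- function(baseEnergy = 3.0,
                           depthSlope = -0.3,
                           tiltSlope = -0.25,
                           noiseSd = 0.05,
                           fMean = 0.3,
                           fSd = 0.05,
                           seed = 1L) {
  new("CouplingParams",
      baseEnergy = baseEnergy, depthSlope = depthSlope,
      tiltSlope = tiltSlope, noiseSd = noiseSd,
      fMean = fMean, fSd = fSd, seed = as.integer(seed))
}

# Rigid probe template in the molecular frame: carbonyl carbon C1 at the
# origin, nitrogen N1 at +0.5 nm along z (the C->N axis defining tilt),
# three ring dummies, and a four-carbon alkyl tail along -z (consecutive
# heavy-atom distances < 0.18 nm so bond detection sees the chain).
.probeTemplate <- function() {
  pos <- rbind(
    C1  = c( 0.00, 0.00,  0.000),
    C2  = c( 0.12, 0.00,  0.125),
    C3  = c( 0.12, 0.00,  0.375),
    C4  = c(-0.12, 0.00,  0.250),
    N1  = c( 0.00, 0.00,  0.500),
    CT1 = c( 0.00, 0.00, -0.152),
    CT2 = c( 0.05, 0.00, -0.290),
    CT3 = c( 0.00, 0.00, -0.440),
    CT4 = c( 0.05, 0.00, -0.578))
  list(positions = pos,
       topology = data.frame(
         name = rownames(pos),
         element = c("C", "C", "C", "C", "N", "C", "C", "C", "C"),
         resid = 1L, resname = "PRB", molid = 1L,
         mass = c(rep(12.011, 4), 14.007, rep(12.011, 4)),
         charge = c(0.30, 0.05, 0.05, 0.00, -0.40, 0, 0, 0, 0),
         stringsAsFactors = FALSE))
}

# Inverse-CDF sampler for a single von Mises-type angular kernel restricted
# to [0, 180] degrees: density proportional to exp(kappa*(cos(theta-mu)-1)).
# Infinite concentration gives the mode exactly.
.sampleAngularKernel <- function(u, modeDeg, concentration) {
  if (!is.finite(concentration)) return(rep(modeDeg, length(u)))
  grid <- seq(0, 180, length.out = 18001L)
  dens <- exp(concentration * (cos(.deg2rad(grid - modeDeg)) - 1))
  cdf <- cumsum(dens)
  cdf <- (cdf - cdf[1]) / (cdf[length(cdf)] - cdf[1])
  stats::approx(x = cdf, y = grid, xout = u, ties = "ordered",
                rule = 2)$y
}

.sampleTiltMixture <- function(n, tiltModel) {
  w <- vapply(tiltModel, function(cmp) cmp$weight, numeric(1))
  comp <- sample.int(length(tiltModel), n, replace = TRUE, prob = w)
  u <- stats::runif(n)
  out <- numeric(n)
  for (k in seq_along(tiltModel)) {
    idx <- comp == k
    if (any(idx))
      out[idx] <- .sampleAngularKernel(u[idx], tiltModel[[k]]$modeDeg,
                                       tiltModel[[k]]$concentration)
  }
  out
}

#' Generate a synthetic bilayer + probe trajectory
#'
#' Draws per-frame tilt (mixture of angular kernels) and penetration depth
#' (Gaussian), places the rigid probe accordingly in the host leaflet with a
#' uniform azimuth and in-plane position, and surrounds it with static
#' phosphate pseudo-atoms on both leaflet planes. The true per-frame tilt
#' and depth are stored in the returned object's metadata
#' (\code{groundTruth(x)}) as the oracle for recovery tests.
#'
#' The probe is placed so that the centre of mass of its fluorophore moiety
#' sits exactly at the drawn depth below the host phosphate plane, and so
#' that its carbonyl-to-nitrogen vector makes exactly the drawn angle with
#' the leaflet-oriented normal; recomputing the observables therefore
#' reproduces the ground truth to rounding error.
#'
#' @param params a \code{TrajectoryParams} object.
#' @return a \code{BilayerTrajectory}; \code{groundTruth()} on it gives a
#'   data.frame \code{(frame, time_ns, tilt_deg, depth_nm)}.
#' @export
generateTrajectory <- function(params) {
  stopifnot(is(params, "TrajectoryParams"))
  validObject(params)
  tmpl <- .probeTemplate()
  nP <- nrow(tmpl$positions)
  nL <- params@nLipidsPerLeaflet
  side <- ceiling(sqrt(nL))
  gx <- ((seq_len(nL) - 1L) %% side + 0.5) * params@box[1] / side
  gy <- ((seq_len(nL) - 1L) %/% side + 0.5) * params@box[2] / side
  phosLower <- cbind(gx, gy, params@phosphatePlaneZ[1])
  phosUpper <- cbind(gx, gy, params@phosphatePlaneZ[2])
  lipTop <- data.frame(
    name = "P", element = "P",
    resid = seq_len(2L * nL) + 1L,
    resname = "LIP", molid = seq_len(2L * nL) + 1L,
    mass = 30.974, charge = 0, stringsAsFactors = FALSE)
  topology <- rbind(tmpl$topology, lipTop)

  nF <- params@nFrames
  upper <- params@leaflet == "upper"
  planeZ <- if (upper) params@phosphatePlaneZ[2] else params@phosphatePlaneZ[1]

  dat <- withSeed(params@seed, {
    tilt <- .sampleTiltMixture(nF, params@tiltModel)
    depth <- if (params@depthModel$sdNm == 0)
      rep(params@depthModel$meanNm, nF)
    else stats::rnorm(nF, params@depthModel$meanNm, params@depthModel$sdNm)
    phi <- stats::runif(nF, 0, 2 * pi)
    x0 <- stats::runif(nF, 0.25 * params@box[1], 0.75 * params@box[1])
    y0 <- stats::runif(nF, 0.25 * params@box[2], 0.75 * params@box[2])
    list(tilt = tilt, depth = depth, phi = phi, x0 = x0, y0 = y0)
  })

  fluorIdx <- match(.fluorophoreAtoms, tmpl$topology$name)
  fluorMass <- tmpl$topology$mass[fluorIdx]
  coords <- array(0, dim = c(nrow(topology), 3, nF))
  for (f in seq_len(nF)) {
    # angle measured from the leaflet-oriented normal: in the lower leaflet
    # "toward water" is -z, so the laboratory polar angle is 180 - tilt
    labTheta <- if (upper) dat$tilt[f] else 180 - dat$tilt[f]
    R <- .rotZ(dat$phi[f]) %*% .rotY(.deg2rad(labTheta))
    rot <- tmpl$positions %*% t(R)
    comF <- .com(rot[fluorIdx, , drop = FALSE], fluorMass)
    targetZ <- if (upper) planeZ - dat$depth[f] else planeZ + dat$depth[f]
    shift <- c(dat$x0[f], dat$y0[f], targetZ) - comF
    probe <- sweep(rot, 2, shift, `+`)
    coords[, , f] <- rbind(probe, phosLower, phosUpper)
  }
  new("BilayerTrajectory",
      coords = coords, topology = topology,
      box = matrix(rep(params@box, each = nF), nF, 3),
      time = (seq_len(nF) - 1) * params@frameInterval,
      metadata = list(
        groundTruth = data.frame(
          frame = seq_len(nF),
          time_ns = (seq_len(nF) - 1) * params@frameInterval,
          tilt_deg = dat$tilt, depth_nm = dat$depth),
        params = params))
}

#' Generate vertical transitions coupled to probe geometry
#'
#' One emission record per descriptor row: the energy is the linear model
#' \code{baseEnergy + depthSlope * depth + tiltSlope * cos(tilt)} plus
#' Gaussian noise, and the oscillator strength a Gaussian draw truncated at
#' zero. Records carry their descriptors so downstream association tests can
#' run without a separate join.
#'
#' @param descriptors data.frame with columns \code{snapshot} (or
#'   \code{frame}), \code{depth_nm}, \code{tilt_deg}.
#' @param params a \code{CouplingParams} object.
#' @param kind "emission" (default) or "absorption".
#' @return an \code{ExcitationSet} annotated with depth and tilt.
#' @export
generateExcitations <- function(descriptors, params, kind = "emission") {
  stopifnot(is(params, "CouplingParams"))
  validObject(params)
  if (is.null(descriptors) || nrow(descriptors) == 0L)
    stop("descriptor list must be non-empty")
  if (!"snapshot" %in% names(descriptors)) {
    if ("frame" %in% names(descriptors))
      descriptors$snapshot <- descriptors$frame
    else stop("descriptors need a 'snapshot' (or 'frame') column")
  }
  if (!all(c("depth_nm", "tilt_deg") %in% names(descriptors)))
    stop("descriptors need 'depth_nm' and 'tilt_deg' columns")
  n <- nrow(descriptors)
  out <- withSeed(params@seed, {
    e <- params@baseEnergy +
      params@depthSlope * descriptors$depth_nm +
      params@tiltSlope * cos(.deg2rad(descriptors$tilt_deg))
    if (params@noiseSd > 0) e <- e + stats::rnorm(n, 0, params@noiseSd)
    f <- if (params@fSd > 0) stats::rnorm(n, params@fMean, params@fSd)
    else rep(params@fMean, n)
    list(e = e, f = pmax(0, f))
  })
  new("ExcitationSet",
      records = data.frame(
        snapshot = descriptors$snapshot,
        state = 1L,
        energy_eV = out$e,
        osc_strength = out$f,
        depth_nm = descriptors$depth_nm,
        tilt_deg = descriptors$tilt_deg,
        stringsAsFactors = FALSE),
      kind = kind)
}

#' Synthesise secondary-trajectory descriptors for the emission protocol
#'
#' The emission sampling protocol re-samples short secondary trajectories
#' spawned from primary snapshots. Running such dynamics is out of scope;
#' for synthetic end-to-end runs each secondary snapshot inherits the
#' primary snapshot's tilt and depth plus a small Gaussian jitter emulating
#' the limited decorrelation of nanosecond-scale secondary dynamics.
#'
#' @param primary data.frame of primary-snapshot descriptors
#'   (\code{snapshot}, \code{depth_nm}, \code{tilt_deg}).
#' @param nSub secondary snapshots per primary snapshot.
#' @param jitterTiltDeg tilt jitter standard deviation, degrees.
#' @param jitterDepthNm depth jitter standard deviation, nm.
#' @param seed integer random seed.
#' @return data.frame with one row per secondary snapshot; \code{snapshot}
#'   is \code{<primary>.<sub>} and tilt is clamped to [0, 180] degrees.
#' @export
syntheticSecondaryDescriptors <- function(primary, nSub = 10L,
                                          jitterTiltDeg = 3,
                                          jitterDepthNm = 0.02,
                                          seed = 1L) {
  if (nrow(primary) == 0L) stop("primary descriptor list must be non-empty")
  nSub <- as.integer(nSub)
  n <- nrow(primary) * nSub
  idx <- rep(seq_len(nrow(primary)), each = nSub)
  withSeed(seed, {
    tilt <- primary$tilt_deg[idx] + stats::rnorm(n, 0, jitterTiltDeg)
    depth <- primary$depth_nm[idx] + stats::rnorm(n, 0, jitterDepthNm)
    data.frame(
      snapshot = paste0(primary$snapshot[idx], ".",
                        rep(seq_len(nSub), nrow(primary))),
      depth_nm = depth,
      tilt_deg = pmin(180, pmax(0, tilt)),
      stringsAsFactors = FALSE)
  })
}
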