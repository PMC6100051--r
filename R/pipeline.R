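#' Assemble a pipeline run configuration
#'
#' A single declarative configuration drives every stage; per-stage
#' sub-lists override the defaults shown here. The configuration can also
#' be read from a YAML file with \code{\link{readRunConfig}}.
#'
#' @param seed master seed; stage seeds default to offsets of it.
#' @param trajectory synthetic-generator arguments (see
#'   \code{\link{trajectoryParams}}) or \code{list(path =, topology =,
#'   format =)} to read a stored trajectory.
#' @param sampling emission-protocol arguments: \code{primaryWindow},
#'   \code{nSecondary}, \code{subWindow}, \code{nSub}, plus
#'   \code{jitterTiltDeg}/\code{jitterDepthNm} for synthetic secondary
#'   descriptors; for absorption: \code{window}, \code{nPrimary},
#'   \code{nRandom}.
#' @param coupling synthetic coupling arguments (see
#'   \code{\link{couplingParams}}), or \code{list(path =)} naming a
#'   vertical-transition table produced by an external engine.
#' @param spectrum \code{delta} (eV FWHM), \code{grid}, band
#'   \code{prominence}.
#' @param histogram \code{tiltBin} (deg), \code{depthBin} (nm).
#' @param correlation \code{enabled}, \code{depthThresh}, \code{tiltThresh},
#'   \code{nPerm}.
#' @param outdir output directory, or NULL to skip writing files.
#' @return a run-configuration list.
#' @export
runConfig <- function(seed = 1L,
                      trajectory = list(),
                      sampling = list(),
                      coupling = list(),
                      spectrum = list(),
                      histogram = list(),
                      correlation = list(),
                      outdir = NULL) {
  seed <- as.integer(seed)
  list(seed = seed,
       trajectory = utils::modifyList(
         list(nFrames = 301L, frameInterval = 0.5, seed = seed), trajectory),
       sampling = utils::modifyList(
         list(primaryWindow = NULL, nSecondary = 22L, subWindow = c(1, 2),
              nSub = 10L, jitterTiltDeg = 3, jitterDepthNm = 0.02,
              window = NULL, nPrimary = 30L, nRandom = 300L), sampling),
       coupling = utils::modifyList(list(seed = seed + 1L), coupling),
       spectrum = utils::modifyList(
         list(delta = 0.1, grid = NULL, prominence = 0.05), spectrum),
       histogram = utils::modifyList(
         list(tiltBin = 5, depthBin = 0.05), histogram),
       correlation = utils::modifyList(
         list(enabled = TRUE, depthThresh = NULL, tiltThresh = 40,
              nPerm = 1000L, seed = seed + 2L), correlation),
       outdir = outdir)
}

#' Gel-phase-like and fluid-phase-like preset configurations
#'
#' The gel-like preset uses a unimodal fluorophore tilt distribution (mode
#' 28 degrees) with deep, narrow penetration; the fluid-like preset a
#' bimodal tilt distribution (modes 28 and 120 degrees) with shallower,
#' wider penetration and the same geometry-to-energy coupling, which
#' yields a second, long-wavelength emission band.
#'
#' @param seed master seed.
#' @param outdir optional output directory.
#' @return a run-configuration list.
#' @export
gelPhaseConfig <- function(seed = 1L, outdir = NULL) {
  runConfig(seed = seed, outdir = outdir,
            trajectory = list(
              tiltModel = list(
                list(modeDeg = 28, concentration = 12, weight = 1)),
              depthModel = list(meanNm = 0.9, sdNm = 0.1)))
}

#' @rdname gelPhaseConfig
#' @export
fluidPhaseConfig <- function(seed = 1L, outdir = NULL) {
  runConfig(seed = seed, outdir = outdir,
            trajectory = list(
              tiltModel = list(
                list(modeDeg = 28, concentration = 12, weight = 0.6),
                list(modeDeg = 120, concentration = 8, weight = 0.4)),
              depthModel = list(meanNm = 0.7, sdNm = 0.2)))
}

#' Read a run configuration from YAML
#'
#' @param path YAML file path.
#' @return a run-configuration list (defaults filled in).
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(runConfig, raw)
}

# stable hash of the configuration for provenance lines
.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

.stageLog <- function(log, stage, message) {
  line <- sprintf("[%s] %s", stage, message)
  c(log, line)
}

.pipelineTrajectory <- function(config) {
  tr <- config$trajectory
  if (!is.null(tr$path)) {
    top <- if (!is.null(tr$topology)) readTopology(tr$topology) else NULL
    fmt <- tr$format %||% if (grepl("\\.gro$", tr$path)) "gro" else "pdb"
    if (fmt == "gro") readTrajectoryGRO(tr$path, topology = top)
    else readTrajectoryPDB(tr$path, topology = top)
  } else {
    args <- tr[setdiff(names(tr), c("path", "topology", "format"))]
    generateTrajectory(do.call(trajectoryParams, args))
  }
}

.writePipelineOutputs <- function(outdir, results, log, hash) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# config_hash: %s", hash)
  wcsv <- function(df, name) {
    path <- file.path(outdir, name)
    con <- file(path, "wt"); writeLines(hdr, con)
    utils::write.csv(df, con, row.names = FALSE); close(con)
  }
  wcsv(results$geometry, "geometry.csv")
  wcsv(manifestEntries(results$manifest), "manifest.csv")
  writeExcitationTable(results$excitations,
                       file.path(outdir, "excitations.csv"))
  writeSpectrum(results$spectrum, file.path(outdir, "spectrum.txt"))
  jsonlite::write_json(results$bands, file.path(outdir, "bands.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (!is.null(results$association)) {
    a <- results$association
    jsonlite::write_json(
      list(config_hash = hash, statistic_eV = a@statistic,
           p_value = a@pValue, depth_thresh_nm = a@depthThresh,
           tilt_thresh_deg = a@tiltThresh,
           group_sizes = as.integer(a@groupSizes), n_perm = a@nPerm),
      file.path(outdir, "association.json"), auto_unbox = TRUE, digits = NA)
  }
  writeLines(c(hdr, log), file.path(outdir, "run.log"))
}

#' Run the emission pipeline end to end
#'
#' Stages: obtain the excited-state trajectory (synthetic or read from
#' disk), compute per-frame tilt/depth, apply the hierarchical emission
#' sampling protocol, obtain vertical transitions for the sampled
#' geometries (synthetic coupling or an external-engine table), synthesise
#' the Lorentzian-broadened emission spectrum, detect bands, and test the
#' deep/low-tilt association. Identical configurations (and seeds) give
#' identical outputs; every output file records the configuration hash.
#'
#' @param config a run-configuration list from \code{\link{runConfig}} (or
#'   a YAML path).
#' @return a list with elements \code{trajectory}, \code{geometry},
#'   \code{manifest}, \code{excitations}, \code{spectrum} (normalised),
#'   \code{bands}, \code{association}, \code{tiltHistogram},
#'   \code{depthHistogram}, \code{configHash}, \code{log}.
#' @export
runEmissionPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  hash <- .configHash(config)
  log <- character()

  traj <- .pipelineTrajectory(config)
  log <- .stageLog(log, "trajectory",
                   sprintf("%d frames, %d atoms", nFrames(traj), nAtoms(traj)))

  geometry <- analyzeGeometry(traj)
  log <- .stageLog(log, "geometry",
                   sprintf("%d frames analysed", nrow(geometry)))

  s <- config$sampling
  manifest <- emissionProtocol(traj, primaryWindow = s$primaryWindow,
                               nSecondary = s$nSecondary,
                               subWindow = s$subWindow, nSub = s$nSub)
  entries <- manifestEntries(manifest)
  log <- .stageLog(log, "sampling",
                   sprintf("%d secondary snapshots from %d seeds",
                           nrow(entries), s$nSecondary))

  if (!is.null(config$coupling$path)) {
    if (!file.exists(config$coupling$path))
      stop("spectra stage: excitation table '", config$coupling$path,
           "' not found")
    exc <- readExcitationTable(config$coupling$path, kind = "emission")
    r <- records(exc)
    if (!all(c("depth_nm", "tilt_deg") %in% names(r)))
      exc <- joinAnnotations(exc, geometry)
  } else {
    seedFrames <- unique(entries$seedFrame)
    primary <- geometry[geometry$frame %in% seedFrames,
                        c("frame", "depth_nm", "tilt_deg")]
    names(primary)[1] <- "snapshot"
    desc <- syntheticSecondaryDescriptors(
      primary, nSub = s$nSub, jitterTiltDeg = s$jitterTiltDeg,
      jitterDepthNm = s$jitterDepthNm, seed = config$seed + 3L)
    cargs <- config$coupling[setdiff(names(config$coupling), "path")]
    exc <- generateExcitations(desc, do.call(couplingParams, cargs),
                               kind = "emission")
  }
  log <- .stageLog(log, "excitations",
                   sprintf("%d records", nrow(records(exc))))

  sp <- config$spectrum
  spec <- normalizeSpectrum(
    ensembleSpectrum(exc, grid = sp$grid, delta = sp$delta))
  bands <- findBands(spec, prominence = sp$prominence)
  log <- .stageLog(log, "spectra",
                   sprintf("%d band(s) above prominence %.3g",
                           nrow(bands), sp$prominence))

  association <- NULL
  if (isTRUE(config$correlation$enabled)) {
    cc <- config$correlation
    association <- testAssociation(exc, depthThresh = cc$depthThresh,
                                   tiltThresh = cc$tiltThresh,
                                   nPerm = cc$nPerm, seed = cc$seed)
    log <- .stageLog(log, "correlation",
                     sprintf("statistic %+.4f eV, p = %.4g",
                             association@statistic, association@pValue))
  }

  hb <- config$histogram
  results <- list(
    trajectory = traj, geometry = geometry, manifest = manifest,
    excitations = exc, spectrum = spec, bands = bands,
    association = association,
    tiltHistogram = buildHistogram(geometry$tilt_deg, hb$tiltBin,
                                   range = c(0, 180)),
    depthHistogram = buildHistogram(geometry$depth_nm, hb$depthBin),
    configHash = hash, log = log)
  if (!is.null(config$outdir))
    .writePipelineOutputs(config$outdir, results, log, hash)
  results
}

#' Run the absorption pipeline end to end
#'
#' Stages: obtain the ground-state trajectory, compute per-frame
#' tilt/depth, select the primary equidistant snapshots and then a random
#' ensemble across the sampling window, obtain vertical transitions for
#' the sampled geometries, and synthesise the Lorentzian-broadened
#' absorption spectrum with band detection. No correlation stage is run
#' for absorption.
#'
#' @param config a run-configuration list from \code{\link{runConfig}}
#'   (or a YAML path).
#' @return a list as for \code{\link{runEmissionPipeline}} (without
#'   \code{association}).
#' @export
runAbsorptionPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  hash <- .configHash(config)
  log <- character()

  traj <- .pipelineTrajectory(config)
  log <- .stageLog(log, "trajectory",
                   sprintf("%d frames, %d atoms", nFrames(traj), nAtoms(traj)))
  geometry <- analyzeGeometry(traj)
  log <- .stageLog(log, "geometry",
                   sprintf("%d frames analysed", nrow(geometry)))

  s <- config$sampling
  window <- s$window %||% range(frameTimes(traj))
  primary <- equidistantSnapshots(
    traj, samplingPlan(window, s$nPrimary, "equidistant"),
    stage = "absorption-primary")
  manifest <- randomSnapshots(
    traj, samplingPlan(window, min(s$nRandom, nFrames(traj)), "random",
                       seed = config$seed + 4L),
    stage = "absorption-random")
  entries <- manifestEntries(manifest)
  log <- .stageLog(log, "sampling",
                   sprintf("%d primary + %d random snapshots",
                           nrow(manifestEntries(primary)), nrow(entries)))

  if (!is.null(config$coupling$path)) {
    if (!file.exists(config$coupling$path))
      stop("spectra stage: excitation table '", config$coupling$path,
           "' not found")
    exc <- readExcitationTable(config$coupling$path, kind = "absorption")
    r <- records(exc)
    if (!all(c("depth_nm", "tilt_deg") %in% names(r)))
      exc <- joinAnnotations(exc, geometry)
  } else {
    desc <- geometry[entries$frame, c("frame", "depth_nm", "tilt_deg")]
    names(desc)[1] <- "snapshot"
    cargs <- utils::modifyList(list(baseEnergy = 3.64, fMean = 0.26),
                               config$coupling[setdiff(
                                 names(config$coupling), "path")])
    exc <- generateExcitations(desc, do.call(couplingParams, cargs),
                               kind = "absorption")
  }
  log <- .stageLog(log, "excitations",
                   sprintf("%d records", nrow(records(exc))))

  sp <- config$spectrum
  spec <- normalizeSpectrum(
    ensembleSpectrum(exc, grid = sp$grid, delta = sp$delta))
  bands <- findBands(spec, prominence = sp$prominence)
  log <- .stageLog(log, "spectra",
                   sprintf("%d band(s) above prominence %.3g",
                           nrow(bands), sp$prominence))

  hb <- config$histogram
  results <- list(
    trajectory = traj, geometry = geometry, manifest = manifest,
    excitations = exc, spectrum = spec, bands = bands,
    association = NULL,
    tiltHistogram = buildHistogram(geometry$tilt_deg, hb$tiltBin,
                                   range = c(0, 180)),
    depthHistogram = buildHistogram(geometry$depth_nm, hb$depthBin),
    configHash = hash, log = log)
  if (!is.null(config$outdir))
    .writePipelineOutputs(config$outdir, results, log, hash)
  results
}
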