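#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame, coordinates in Angstrom, box as a
#' CRYST1 record (orthorhombic). Masses and partial charges do not fit the
#' PDB format; pair the file with \code{\link{writeTopology}}.
#'
#' @param x a \code{BilayerTrajectory}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeTrajectoryPDB <- function(x, path) {
  stopifnot(is(x, "BilayerTrajectory"))
  top <- x@topology
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    x@box[1, 1] * 10, x@box[1, 2] * 10, x@box[1, 3] * 10, 90, 90, 90), con)
  nm <- ifelse(nchar(top$name) < 4L,
               sprintf(" %-3s", top$name), sprintf("%-4s", top$name))
  for (f in seq_len(nFrames(x))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    pos <- frameCoords(x, f) * 10  # nm -> Angstrom
    writeLines(sprintf(
      "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(top)), nm, substr(top$resname, 1, 3), "A",
      top$resid %% 10000L, pos[, 1], pos[, 2], pos[, 3], 1, 0,
      toupper(top$element)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file into a trajectory
#'
#' Uses \code{bio3d} for PDB parsing. A topology table (from
#' \code{\link{readTopology}}) supplies masses and charges; without one,
#' masses are guessed from the element and charges set to zero.
#'
#' @param path PDB file path.
#' @param topology optional topology data.frame matching the file's atoms.
#' @param frameInterval time between frames in ns (PDB stores no times).
#' @return a \code{BilayerTrajectory}.
#' @export
readTrajectoryPDB <- function(path, topology = NULL, frameInterval = 1) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3L
  coords <- array(0, dim = c(na, 3, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE) / 10  # A -> nm
  if (is.null(topology)) {
    elem <- trimws(pdb$atom$elesy)
    if (all(elem == "" | is.na(elem)))
      elem <- substr(trimws(pdb$atom$elety), 1, 1)
    key <- paste(pdb$atom$resno, pdb$atom$resid)
    topology <- data.frame(
      name = trimws(pdb$atom$elety),
      element = elem,
      resid = pdb$atom$resno,
      resname = trimws(pdb$atom$resid),
      molid = as.integer(factor(key, levels = unique(key))),
      mass = .elementMass(elem),
      charge = 0,
      stringsAsFactors = FALSE)
  }
  box <- .readCryst1Box(path)
  if (is.null(box)) box <- apply(coords, 2, max) - apply(coords, 2, min) + 1
  new("BilayerTrajectory",
      coords = coords, topology = topology,
      box = matrix(rep(box, each = nf), nf, 3),
      time = (seq_len(nf) - 1) * frameInterval,
      metadata = list(source = path))
}

.readCryst1Box <- function(path) {
  ln <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (!length(ln)) return(NULL)
  as.numeric(c(substr(ln[1], 7, 15), substr(ln[1], 16, 24),
               substr(ln[1], 25, 33))) / 10
}

.elementMass <- function(elem) {
  tbl <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
           S = 32.06)
  m <- tbl[toupper(substr(elem, 1, 1))]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Write a trajectory as a GRO frame sequence
#'
#' Frames are concatenated in one file in GROMACS .gro fixed-width format
#' (positions in nm, frame time on the title line).
#'
#' @param x a \code{BilayerTrajectory}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeTrajectoryGRO <- function(x, path) {
  stopifnot(is(x, "BilayerTrajectory"))
  top <- x@topology
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in seq_len(nFrames(x))) {
    writeLines(sprintf("synthetic bilayer frame, t= %.6f", x@time[f]), con)
    writeLines(sprintf("%d", nAtoms(x)), con)
    pos <- frameCoords(x, f)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       top$resid %% 100000L, substr(top$resname, 1, 5),
                       substr(top$name, 1, 5),
                       seq_len(nrow(top)) %% 100000L,
                       pos[, 1], pos[, 2], pos[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f",
                       x@box[f, 1], x@box[f, 2], x@box[f, 3]), con)
  }
  invisible(path)
}

#' Read a GRO frame sequence into a trajectory
#'
#' @param path GRO file path (one or more concatenated frames).
#' @param topology optional topology data.frame; without one masses are
#'   guessed from the first letter of the atom name and charges set to zero.
#' @return a \code{BilayerTrajectory}.
#' @export
readTrajectoryGRO <- function(path, topology = NULL) {
  ln <- readLines(path, warn = FALSE)
  frames <- list(); boxes <- list(); times <- numeric()
  i <- 1L
  topo0 <- NULL
  while (i <= length(ln)) {
    title <- ln[i]
    na <- as.integer(trimws(ln[i + 1L]))
    atomLines <- ln[(i + 2L):(i + 1L + na)]
    boxLine <- ln[i + 2L + na]
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    times <- c(times, if (length(tm))
      as.numeric(sub("t=\\s*", "", tm)) else length(times))
    pos <- cbind(as.numeric(substr(atomLines, 21, 28)),
                 as.numeric(substr(atomLines, 29, 36)),
                 as.numeric(substr(atomLines, 37, 44)))
    frames[[length(frames) + 1L]] <- pos
    boxes[[length(boxes) + 1L]] <- as.numeric(
      strsplit(trimws(boxLine), "\\s+")[[1]])[1:3]
    if (is.null(topo0)) {
      nm <- trimws(substr(atomLines, 11, 15))
      topo0 <- data.frame(
        name = nm,
        element = substr(nm, 1, 1),
        resid = as.integer(substr(atomLines, 1, 5)),
        resname = trimws(substr(atomLines, 6, 10)),
        molid = as.integer(factor(substr(atomLines, 1, 10),
                                  levels = unique(substr(atomLines, 1, 10)))),
        mass = .elementMass(substr(nm, 1, 1)),
        charge = 0,
        stringsAsFactors = FALSE)
    }
    i <- i + 3L + na
  }
  if (!is.null(topology)) topo0 <- topology
  nf <- length(frames)
  coords <- array(0, dim = c(nrow(frames[[1]]), 3, nf))
  for (f in seq_len(nf)) coords[, , f] <- frames[[f]]
  new("BilayerTrajectory",
      coords = coords, topology = topo0,
      box = do.call(rbind, boxes), time = times,
      metadata = list(source = path))
}

#' Write / read the topology table
#'
#' Atom names, elements, residue membership, molecule ids, masses and
#' partial charges as delimited text (CSV).
#'
#' @param topology a topology data.frame (columns \code{name},
#'   \code{element}, \code{resid}, \code{resname}, \code{molid},
#'   \code{mass}, \code{charge}).
#' @param path file path.
#' @return \code{writeTopology} the path invisibly; \code{readTopology}
#'   the validated data.frame.
#' @export
writeTopology <- function(topology, path) {
  if (!all(.topologyColumns %in% names(topology)))
    stop("topology must contain columns: ",
         paste(.topologyColumns, collapse = ", "))
  utils::write.csv(topology[, .topologyColumns], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTopology
#' @export
readTopology <- function(path) {
  top <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(.topologyColumns %in% names(top)))
    stop("topology file missing columns: ",
         paste(setdiff(.topologyColumns, names(top)), collapse = ", "))
  top
}

#' Write generator ground truth as CSV
#'
#' Per-frame true tilt (degrees) and penetration depth (nm) of a synthetic
#' trajectory, used as the oracle in recovery tests.
#'
#' @param x a synthetic \code{BilayerTrajectory} carrying ground truth.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writeGroundTruth <- function(x, path) {
  gt <- groundTruth(x)
  if (is.null(gt)) stop("trajectory carries no ground truth")
  utils::write.csv(gt, path, row.names = FALSE)
  invisible(path)
}
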