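# Distance-based bond detection within one molecule: heavy-heavy pairs
# closer than 0.18 nm, pairs involving hydrogen closer than 0.13 nm.
.bondGraph <- function(positions, elements) {
  n <- nrow(positions)
  adj <- vector("list", n)
  isH <- toupper(elements) == "H"
  for (i in seq_len(n - 1L)) {
    d <- sqrt(colSums((t(positions[(i + 1L):n, , drop = FALSE]) -
                         positions[i, ])^2))
    cut <- ifelse(isH[i] | isH[(i + 1L):n], 0.13, 0.18)
    js <- which(d < cut) + i
    adj[[i]] <- c(adj[[i]], js)
    for (j in js) adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

.reachable <- function(adj, from, blockedEdge = NULL) {
  n <- length(adj)
  seen <- logical(n)
  queue <- from
  seen[from] <- TRUE
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    for (j in adj[[i]]) {
      if (!is.null(blockedEdge) &&
          ((i == blockedEdge[1] && j == blockedEdge[2]) ||
           (i == blockedEdge[2] && j == blockedEdge[1]))) next
      if (!seen[j]) { seen[j] <- TRUE; queue <- c(queue, j) }
    }
  }
  which(seen)
}

#' Truncate the probe to its fluorophore, capping with a methyl hydrogen
#'
#' Removes the alkyl tail beyond a cut bond and caps the retained carbon to
#' a methyl group by placing a link hydrogen along the cut-bond direction at
#' the standard C-H distance of 0.109 nm. The alkyl chain carries no
#' frontier orbitals, so this truncation leaves the excitation physics of
#' the fluorophore intact while shrinking the quantum region.
#'
#' Bonds are detected by interatomic distance within the probe molecule. A
#' cut bond that is part of a ring (its two atoms remain connected after
#' removing the bond) raises an error.
#'
#' @param x a \code{BilayerTrajectory}.
#' @param frame frame index.
#' @param cutBond length-2 character vector \code{c(kept, removed)}: the
#'   atom kept in the fragment and the first tail atom to remove.
#' @return a \code{QMFragment}; its metadata-free slots carry the retained
#'   atoms, the link-hydrogen record, and the molecule's integer net charge.
#' @export
truncateToFluorophore <- function(x, frame = 1L, cutBond = c("C1", "CT1")) {
  top <- x@topology
  iKept <- .resolveSingleAtom(top, cutBond[1])
  iRem <- .resolveSingleAtom(top, cutBond[2])
  mol <- top$molid[iKept]
  if (top$molid[iRem] != mol)
    stop("cut bond atoms belong to different molecules")
  probe <- which(top$molid == mol)
  pos <- makeWhole(frameCoords(x, frame)[probe, , drop = FALSE],
                   x@box[frame, ])
  elements <- top$element[probe]
  pk <- match(iKept, probe); pr <- match(iRem, probe)
  adj <- .bondGraph(pos, elements)
  if (!pr %in% adj[[pk]])
    stop("cut bond ", cutBond[1], "-", cutBond[2],
         " not found among detected bonds")
  stillConnected <- pk %in% .reachable(adj, pr, blockedEdge = c(pk, pr))
  if (stillConnected)
    stop("topology error: cut bond ", cutBond[1], "-", cutBond[2],
         " lies inside a ring")
  tail <- .reachable(adj, pr, blockedEdge = c(pk, pr))
  keep <- setdiff(seq_along(probe), tail)
  dirv <- pos[pr, ] - pos[pk, ]
  dirv <- dirv / sqrt(sum(dirv^2))
  hPos <- pos[pk, ] + 0.109 * dirv
  atoms <- data.frame(name = c(top$name[probe][keep], "HL"),
                      element = c(elements[keep], "H"),
                      stringsAsFactors = FALSE)
  new("QMFragment",
      atoms = atoms,
      positions = rbind(pos[keep, , drop = FALSE], hPos),
      netCharge = round(sum(top$charge[probe])),
      linkAtoms = data.frame(kept = cutBond[1], removed = cutBond[2],
                             hx = hPos[1], hy = hPos[2], hz = hPos[3],
                             stringsAsFactors = FALSE))
}

#' Build the point-charge environment around a quantum region
#'
#' Every atom outside the quantum selection becomes a fixed point charge at
#' its force-field partial charge. Environment molecules are treated whole:
#' a molecule is included entirely or not at all, and each included
#' molecule is first made whole across periodic boundaries and then shifted
#' as a unit into the minimum image relative to the quantum region's centre
#' of mass, so intramolecular geometry is never distorted and no artificial
#' net charges arise. No distance cutoff is applied by default.
#'
#' If the quantum selection is a strict subset of its molecule (a truncated
#' fluorophore), the remaining tail atoms are handled by the link-atom
#' charge rule: tail charges on atoms bonded to the quantum region are
#' zeroed and their total spread uniformly over the remaining tail atoms,
#' preserving the molecule's net charge (\code{tailRule = "spread"});
#' \code{tailRule = "exclude"} drops the tail entirely.
#'
#' @param x a \code{BilayerTrajectory}.
#' @param frame frame index.
#' @param qmSelection atom names or indices of the quantum region.
#' @param cutoff optional molecule-COM distance cutoff in nm (default
#'   \code{Inf}: no cutoff).
#' @param rMin closest allowed environment-QM contact in nm; closer
#'   contacts trigger a warning (they usually indicate a broken wrap), not
#'   exclusion.
#' @param tailRule "spread" or "exclude"; see Details.
#' @return a \code{ChargeEnvironment} in nm.
#' @export
buildEnvironment <- function(x, frame = 1L, qmSelection,
                             cutoff = Inf, rMin = 0.05,
                             tailRule = c("spread", "exclude")) {
  tailRule <- match.arg(tailRule)
  top <- x@topology
  qmIdx <- .resolveSelection(top, qmSelection)
  if (anyNA(top$charge))
    stop("topology error: missing partial charges")
  box <- x@box[frame, ]
  pos <- frameCoords(x, frame)
  qmPos <- makeWhole(pos[qmIdx, , drop = FALSE], box)
  qmCOM <- .com(qmPos, top$mass[qmIdx])

  qmMols <- unique(top$molid[qmIdx])
  envIdx <- integer(); envQ <- numeric(); envMol <- integer()
  envPos <- NULL

  # tail of a partially quantum molecule, under the link-atom charge rule
  for (m in qmMols) {
    molAtoms <- which(top$molid == m)
    tailA <- setdiff(molAtoms, qmIdx)
    if (!length(tailA) || tailRule == "exclude") next
    molPos <- makeWhole(pos[molAtoms, , drop = FALSE], box)
    q <- top$charge[tailA]
    tp <- molPos[match(tailA, molAtoms), , drop = FALSE]
    qp <- molPos[match(intersect(molAtoms, qmIdx), molAtoms), , drop = FALSE]
    mind <- apply(tp, 1, function(p)
      min(sqrt(colSums((t(qp) - p)^2))))
    boundary <- mind < 0.18
    if (any(boundary) && any(!boundary)) {
      moved <- sum(q[boundary])
      q[boundary] <- 0
      q[!boundary] <- q[!boundary] + moved / sum(!boundary)
    } else if (all(boundary)) {
      q[] <- sum(q) / length(q)
    }
    envIdx <- c(envIdx, tailA)
    envQ <- c(envQ, q)
    envMol <- c(envMol, rep(m, length(tailA)))
    envPos <- rbind(envPos, tp)
  }

  # whole environment molecules, minimum-imaged as units about the QM COM
  otherMols <- setdiff(unique(top$molid), qmMols)
  for (m in otherMols) {
    molAtoms <- which(top$molid == m)
    molPos <- makeWhole(pos[molAtoms, , drop = FALSE], box)
    com <- .com(molPos, top$mass[molAtoms])
    shift <- -box * round((com - qmCOM) / box)
    molPos <- sweep(molPos, 2, shift, `+`)
    if (is.finite(cutoff) &&
        sqrt(sum((com + shift - qmCOM)^2)) > cutoff) next
    envIdx <- c(envIdx, molAtoms)
    envQ <- c(envQ, top$charge[molAtoms])
    envMol <- c(envMol, rep(m, length(molAtoms)))
    envPos <- rbind(envPos, molPos)
  }

  if (is.null(envPos)) {
    envPos <- matrix(numeric(0), 0, 3)
  } else {
    mind <- min(apply(envPos, 1, function(p)
      min(sqrt(colSums((t(qmPos) - p)^2)))))
    if (mind < rMin)
      warning(sprintf(
        "environment point within %.3g nm of the QM region (< rMin = %g nm); check wrapping",
        mind, rMin))
  }
  colnames(envPos) <- c("x", "y", "z")
  new("ChargeEnvironment", positions = envPos, charges = envQ,
      molids = as.integer(envMol), units = "nm")
}

#' Write / read a point-charge file
#'
#' Whitespace-delimited text, one point per line: \code{x y z q} with fixed
#' 10-decimal formatting. Positions are written in nm by default or in
#' Bohr with \code{units = "bohr"}; a round-trip read reproduces the values
#' exactly at the written precision.
#'
#' @param env a \code{ChargeEnvironment}.
#' @param path file path.
#' @param units "nm" or "bohr".
#' @return \code{writePointCharges} the path invisibly;
#'   \code{readPointCharges} a \code{ChargeEnvironment}.
#' @export
writePointCharges <- function(env, path, units = c("nm", "bohr")) {
  units <- match.arg(units)
  stopifnot(is(env, "ChargeEnvironment"))
  pos <- env@positions
  if (units == "bohr" && env@units == "nm") pos <- pos / .nm_per_bohr
  if (units == "nm" && env@units == "bohr") pos <- pos * .nm_per_bohr
  if (nrow(pos) == 0L) {
    file.create(path)
    warning("writing an empty point-charge environment")
    return(invisible(path))
  }
  writeLines(sprintf("%.10f %.10f %.10f %.10f",
                     pos[, 1], pos[, 2], pos[, 3], env@charges), path)
  invisible(path)
}

#' @rdname writePointCharges
#' @export
readPointCharges <- function(path, units = c("nm", "bohr")) {
  units <- match.arg(units)
  if (file.size(path) == 0L)
    return(new("ChargeEnvironment",
               positions = matrix(numeric(0), 0, 3,
                                  dimnames = list(NULL, c("x", "y", "z"))),
               charges = numeric(0), molids = integer(0), units = units))
  m <- as.matrix(utils::read.table(path, col.names = c("x", "y", "z", "q")))
  new("ChargeEnvironment",
      positions = m[, 1:3, drop = FALSE],
      charges = unname(m[, 4]),
      molids = seq_len(nrow(m)),
      units = units)
}

#' Write a quantum fragment as an XYZ file
#'
#' Standard XYZ format with positions in Angstrom.
#'
#' @param fragment a \code{QMFragment}.
#' @param path file path.
#' @param comment second-line comment.
#' @return invisibly, the path.
#' @export
writeXYZ <- function(fragment, path, comment = "quantum fragment") {
  stopifnot(is(fragment, "QMFragment"))
  pos <- fragment@positions * 10  # nm -> Angstrom
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(sprintf("%d", nrow(pos)), comment), con)
  writeLines(sprintf("%-2s %14.8f %14.8f %14.8f",
                     fragment@atoms$element, pos[, 1], pos[, 2], pos[, 3]),
             con)
  invisible(path)
}
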