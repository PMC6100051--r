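# Build a one-frame bilayer trajectory by hand: an arbitrary set of probe
# atoms plus phosphate pseudo-atoms on two planes. Used to pin down the
# geometric conventions with exactly placed coordinates.
makeFrame <- function(probePos,
                      probeNames = rownames(probePos),
                      probeElements = substr(probeNames, 1, 1),
                      probeMasses = ifelse(probeElements == "N",
                                           14.007, 12.011),
                      probeCharges = rep(0, nrow(probePos)),
                      phosLowerZ = 1.5, phosUpperZ = 3.5,
                      box = c(6, 6, 5), nPhos = 4L) {
  gx <- ((seq_len(nPhos) - 1L) %% 2 + 0.5) * box[1] / 2
  gy <- ((seq_len(nPhos) - 1L) %/% 2 + 0.5) * box[2] / 2
  phos <- rbind(cbind(gx, gy, phosLowerZ), cbind(gx, gy, phosUpperZ))
  coords <- rbind(probePos, phos)
  topology <- data.frame(
    name = c(probeNames, rep("P", 2L * nPhos)),
    element = c(probeElements, rep("P", 2L * nPhos)),
    resid = c(rep(1L, nrow(probePos)), seq_len(2L * nPhos) + 1L),
    resname = c(rep("PRB", nrow(probePos)), rep("LIP", 2L * nPhos)),
    molid = c(rep(1L, nrow(probePos)), seq_len(2L * nPhos) + 1L),
    mass = c(probeMasses, rep(30.974, 2L * nPhos)),
    charge = c(probeCharges, rep(0, 2L * nPhos)),
    stringsAsFactors = FALSE)
  bilayerTrajectory(coords, topology, box)
}

# Probe with C1 -> N1 along a chosen direction, translated by `at`. Extra
# fluorophore dummies keep the default depth selection resolvable.
makeProbeFrame <- function(cn = c(0, 0, 0.5), at = c(3, 3, 3), ...) {
  d <- cn / sqrt(sum(cn^2))
  # two dummies off-axis so the fluorophore set has >= 3 distinct atoms
  perp <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  perp <- perp - sum(perp * d) * d
  perp <- perp / sqrt(sum(perp^2))
  pos <- rbind(C1 = c(0, 0, 0),
               N1 = cn,
               C2 = cn / 2 + 0.1 * perp,
               C3 = cn / 4 - 0.1 * perp,
               C4 = 3 * cn / 4)
  pos <- sweep(pos, 2, at, `+`)
  makeFrame(pos, ...)
}

# A fast, topology-light trajectory (two atoms, linear times) for
# sampling-protocol tests where only frame times matter.
makeTimeline <- function(nFrames, frameInterval = 1) {
  coords <- array(0, dim = c(2, 3, nFrames))
  coords[2, 3, ] <- 1
  topology <- data.frame(
    name = c("C1", "N1"), element = c("C", "N"), resid = 1L,
    resname = "PRB", molid = 1L, mass = c(12.011, 14.007), charge = 0,
    stringsAsFactors = FALSE)
  bilayerTrajectory(coords, topology, box = c(5, 5, 5),
                    time = (seq_len(nFrames) - 1) * frameInterval)
}

# Three rigid three-site waters at given oxygen positions (TIP3P-like
# charges), as an environment fixture.
makeWaterBox <- function(oxygenZ = c(4.2, 4.4, 4.6), box = c(6, 6, 5),
                         probePos = NULL) {
  waters <- do.call(rbind, lapply(seq_along(oxygenZ), function(i) {
    o <- c(1 + 0.3 * i, 1, oxygenZ[i])
    rbind(o, o + c(0.095, 0, 0.02), o + c(-0.03, 0.09, 0.02))
  }))
  if (is.null(probePos))
    probePos <- rbind(C1 = c(3, 3, 3), N1 = c(3, 3, 3.5))
  coords <- rbind(probePos, waters)
  nW <- length(oxygenZ)
  topology <- data.frame(
    name = c(rownames(probePos), rep(c("OW", "HW1", "HW2"), nW)),
    element = c(substr(rownames(probePos), 1, 1),
                rep(c("O", "H", "H"), nW)),
    resid = c(rep(1L, nrow(probePos)), rep(seq_len(nW) + 1L, each = 3L)),
    resname = c(rep("PRB", nrow(probePos)), rep("SOL", 3L * nW)),
    molid = c(rep(1L, nrow(probePos)), rep(seq_len(nW) + 1L, each = 3L)),
    mass = c(ifelse(substr(rownames(probePos), 1, 1) == "N",
                    14.007, 12.011),
             rep(c(15.999, 1.008, 1.008), nW)),
    charge = c(rep(0, nrow(probePos)), rep(c(-0.834, 0.417, 0.417), nW)),
    stringsAsFactors = FALSE)
  bilayerTrajectory(coords, topology, box)
}
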