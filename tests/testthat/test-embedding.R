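test_that("alkyl-tail truncation removes the tail and caps with a link hydrogen", {
  tr <- generateTrajectory(trajectoryParams(nFrames = 3L, seed = 6L))
  frag <- truncateToFluorophore(tr, frame = 2L, cutBond = c("C1", "CT1"))
  expect_false(any(grepl("^CT", frag@atoms$name)))
  expect_true("HL" %in% frag@atoms$name)
  # bookkeeping: probe atoms - 4 tail carbons + 1 link hydrogen
  probeN <- sum(topology(tr)$resname == "PRB")
  expect_equal(nrow(frag@atoms), probeN - 4L + 1L)
  # link H collinear with the cut bond at 0.109 nm from the kept carbon
  pos <- frameCoords(tr, 2L)
  iC <- which(topology(tr)$name == "C1")
  iT <- which(topology(tr)$name == "CT1")
  dirv <- pos[iT, ] - pos[iC, ]
  dirv <- dirv / sqrt(sum(dirv^2))
  h <- unlist(frag@linkAtoms[1, c("hx", "hy", "hz")], use.names = FALSE)
  expect_equal(h, unname(pos[iC, ] + 0.109 * dirv), tolerance = 1e-9)
  expect_equal(sqrt(sum((h - pos[iC, ])^2)), 0.109, tolerance = 1e-12)
  expect_equal(frag@netCharge, 0)
})

test_that("cutting inside a ring is refused", {
  # an equilateral triangle of carbons: every bond is a ring bond
  r <- 0.15
  ringPos <- rbind(R1 = c(3, 3, 3),
                   R2 = c(3 + r, 3, 3),
                   R3 = c(3 + r / 2, 3 + r * sqrt(3) / 2, 3))
  fr <- makeFrame(ringPos)
  expect_error(truncateToFluorophore(fr, cutBond = c("R1", "R2")),
               "ring")
})

test_that("water environments give whole neutral molecules", {
  fr <- makeWaterBox()
  env <- buildEnvironment(fr, qmSelection = c("C1", "N1"))
  expect_equal(length(env@charges), 9L)
  expect_lt(abs(totalCharge(env)), 1e-9)
  # whole-molecule inclusion: each molecule contributes all of its atoms
  expect_true(all(table(env@molids) == 3L))
})

test_that("environment molecules are minimum-imaged whole about the QM region", {
  # probe near the box corner; waters across the boundary
  probe <- rbind(C1 = c(0.1, 0.1, 0.2), N1 = c(0.1, 0.1, 0.7))
  fr <- makeWaterBox(oxygenZ = c(4.6, 4.8, 0.4), probePos = probe)
  env <- buildEnvironment(fr, qmSelection = c("C1", "N1"))
  box <- boxVectors(fr)[1, ]
  top <- topology(fr)
  qmIdx <- match(c("C1", "N1"), top$name)
  qmCOM <- colSums(frameCoords(fr, 1)[qmIdx, ] *
                     top$mass[qmIdx]) / sum(top$mass[qmIdx])
  # every environment point lies within half a box of the QM centre of mass
  for (k in 1:3)
    expect_true(all(abs(env@positions[, k] - qmCOM[k]) <= box[k] / 2 + 0.12))
  # wrapping preserved intramolecular geometry: O-H distances ~0.097 nm
  for (m in unique(env@molids)) {
    p <- env@positions[env@molids == m, ]
    dOH <- sqrt(sum((p[2, ] - p[1, ])^2))
    expect_lt(dOH, 0.12)
  }
})

test_that("a partially quantum molecule's tail follows the link-atom charge rule", {
  tr <- generateTrajectory(trajectoryParams(nFrames = 1L, seed = 2L))
  top <- topology(tr)
  qm <- c("C1", "N1", "C2", "C3", "C4")
  env <- buildEnvironment(tr, qmSelection = qm, tailRule = "spread")
  # the four tail carbons remain as point charges; lipids add 128 more
  expect_equal(length(env@charges), 4L + 128L)
  # tail total charge preserved (all-zero in the synthetic template)
  tailQ <- env@charges[seq_len(4L)]
  expect_equal(sum(tailQ), sum(top$charge[grepl("^CT", top$name)]),
               tolerance = 1e-12)
  # the boundary tail atom's charge is zeroed
  expect_equal(tailQ[1], 0)
  env2 <- buildEnvironment(tr, qmSelection = qm, tailRule = "exclude")
  expect_equal(length(env2@charges), 128L)
})

test_that("environment total charge equals the sum of included molecule charges", {
  tr <- generateTrajectory(trajectoryParams(nFrames = 1L, seed = 3L))
  probeAtoms <- topology(tr)$name[topology(tr)$resname == "PRB"]
  env <- buildEnvironment(tr, qmSelection = probeAtoms)
  expect_equal(totalCharge(env), 0, tolerance = 1e-9)
})

test_that("close contacts warn rather than silently excluding points", {
  probe <- rbind(C1 = c(3, 3, 3), N1 = c(3, 3, 3.5))
  fr <- makeWaterBox(oxygenZ = 3.02, probePos = probe)  # O at ~0.02 nm above C1? no: x differs
  # place a water oxygen essentially on top of the probe
  coords <- frameCoords(fr, 1)
  ow <- which(topology(fr)$name == "OW")[1]
  coords[ow, ] <- c(3, 3, 3.01)
  fr2 <- bilayerTrajectory(coords, topology(fr), boxVectors(fr)[1, ])
  expect_warning(buildEnvironment(fr2, qmSelection = c("C1", "N1")),
                 "rMin")
})

test_that("point-charge files round-trip at the written precision", {
  fr <- makeWaterBox()
  env <- buildEnvironment(fr, qmSelection = c("C1", "N1"))
  path <- withr::local_tempfile(fileext = ".pc")
  writePointCharges(env, path)
  back <- readPointCharges(path)
  expect_equal(back@charges, env@charges, tolerance = 1e-10)
  expect_equal(unname(back@positions), unname(env@positions),
               tolerance = 1e-10)
  expect_equal(length(readLines(path)), 9L)
  expect_lt(abs(sum(back@charges)), 1e-9)
  # Bohr units round-trip through the conversion
  writePointCharges(env, path, units = "bohr")
  bohr <- readPointCharges(path, units = "bohr")
  expect_equal(unname(bohr@positions) * 0.052917721,
               unname(env@positions), tolerance = 1e-8)
  # empty environment: empty file plus a warning
  empty <- new("ChargeEnvironment",
               positions = matrix(numeric(0), 0, 3),
               charges = numeric(0), molids = integer(0), units = "nm")
  expect_warning(writePointCharges(empty, path), "empty")
  expect_equal(file.size(path), 0)
})

test_that("XYZ export writes the fragment in Angstrom", {
  tr <- generateTrajectory(trajectoryParams(nFrames = 1L, seed = 4L))
  frag <- truncateToFluorophore(tr)
  path <- withr::local_tempfile(fileext = ".xyz")
  writeXYZ(frag, path)
  ln <- readLines(path)
  expect_equal(as.integer(ln[1]), nrow(frag@atoms))
  fields <- strsplit(trimws(ln[3]), "\\s+")[[1]]
  expect_equal(as.numeric(fields[2:4]), unname(frag@positions[1, ] * 10),
               tolerance = 1e-6)
})
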