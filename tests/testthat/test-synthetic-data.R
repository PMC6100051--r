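test_that("degenerate distributions are reproduced exactly by the observables", {
  # point-mass tilt at 0 degrees
  p0 <- trajectoryParams(
    nFrames = 10L,
    tiltModel = list(list(modeDeg = 0, concentration = Inf, weight = 1)),
    depthModel = list(meanNm = 0.8, sdNm = 0), seed = 11L)
  tr <- generateTrajectory(p0)
  g <- analyzeGeometry(tr)
  expect_true(all(abs(g$tilt_deg) < 1e-6))
  # zero-variance depth
  expect_true(all(abs(g$depth_nm - 0.8) < 1e-9))
})

test_that("recomputed observables match the generator ground truth", {
  tr <- generateTrajectory(trajectoryParams(nFrames = 40L, seed = 5L))
  g <- analyzeGeometry(tr)
  gt <- groundTruth(tr)
  expect_equal(g$tilt_deg, gt$tilt_deg, tolerance = 1e-9)
  expect_equal(g$depth_nm, gt$depth_nm, tolerance = 1e-9)
})

test_that("the lower-leaflet probe reproduces ground truth under the flipped normal", {
  p <- trajectoryParams(nFrames = 25L, leaflet = "lower", seed = 9L)
  tr <- generateTrajectory(p)
  g <- analyzeGeometry(tr)
  gt <- groundTruth(tr)
  expect_equal(g$tilt_deg, gt$tilt_deg, tolerance = 1e-9)
  expect_equal(g$depth_nm, gt$depth_nm, tolerance = 1e-9)
})

test_that("regeneration with the same seed is bit-identical", {
  p <- trajectoryParams(nFrames = 15L, seed = 42L)
  a <- generateTrajectory(p)
  b <- generateTrajectory(p)
  expect_identical(frameCoords(a), frameCoords(b))
  expect_identical(groundTruth(a), groundTruth(b))
  cp <- couplingParams(seed = 42L)
  d <- groundTruth(a)[, c("frame", "depth_nm", "tilt_deg")]
  names(d)[1] <- "snapshot"
  expect_identical(records(generateExcitations(d, cp)),
                   records(generateExcitations(d, cp)))
})

test_that("generated depths converge to the depth model", {
  p <- trajectoryParams(nFrames = 4000L,
                        depthModel = list(meanNm = 0.8, sdNm = 0.15),
                        seed = 3L)
  d <- groundTruth(generateTrajectory(p))$depth_nm
  se <- 0.15 / sqrt(length(d))
  expect_lt(abs(mean(d) - 0.8), 3 * se)
  expect_lt(abs(sd(d) - 0.15), 3 * 0.15 / sqrt(2 * (length(d) - 1)))
})

test_that("the tilt mixture sampler recovers both modes of a bimodal model", {
  p <- trajectoryParams(
    nFrames = 8000L,
    tiltModel = list(list(modeDeg = 28, concentration = 12, weight = 0.5),
                     list(modeDeg = 120, concentration = 12, weight = 0.5)),
    seed = 21L)
  tilt <- groundTruth(generateTrajectory(p))$tilt_deg
  h <- buildHistogram(tilt, binWidth = 5, range = c(0, 180))
  modes <- localModes(h, minProminence = 0.2)
  expect_length(modes, 2L)
  expect_lt(abs(modes[1] - 28), 5)
  expect_lt(abs(modes[2] - 120), 5)
})

test_that("excitation coupling follows the linear model", {
  d <- data.frame(snapshot = 1:50,
                  depth_nm = seq(0.2, 1.4, length.out = 50),
                  tilt_deg = seq(5, 170, length.out = 50))
  # no slopes, no noise: all energies at the base
  e0 <- records(generateExcitations(
    d, couplingParams(baseEnergy = 3, depthSlope = 0, tiltSlope = 0,
                      noiseSd = 0, fSd = 0)))
  expect_true(all(e0$energy_eV == 3))
  # negative depth slope, no noise: energy strictly decreasing in depth
  e1 <- records(generateExcitations(
    d, couplingParams(baseEnergy = 3, depthSlope = -0.5, tiltSlope = 0,
                      noiseSd = 0)))
  expect_equal(cor(e1$energy_eV, e1$depth_nm, method = "spearman"), -1)
})

test_that("oscillator strengths are never negative and inputs are validated", {
  d <- data.frame(snapshot = 1:500, depth_nm = 0.8, tilt_deg = 28)
  r <- records(generateExcitations(
    d, couplingParams(fMean = 0.05, fSd = 0.2, seed = 2L)))
  expect_true(all(r$osc_strength >= 0))
  expect_error(generateExcitations(d[0, ], couplingParams()), "non-empty")
  expect_error(trajectoryParams(nFrames = 0), "nFrames")
  expect_error(trajectoryParams(
    tiltModel = list(list(modeDeg = 28, concentration = 5, weight = 0.7))),
    "sum to 1")
  expect_error(couplingParams(noiseSd = -1), "noiseSd")
})

test_that("secondary descriptors jitter around their primaries", {
  primary <- data.frame(snapshot = 1:5, depth_nm = 0.8, tilt_deg = 28)
  d <- syntheticSecondaryDescriptors(primary, nSub = 10, seed = 4L)
  expect_equal(nrow(d), 50L)
  expect_true(all(d$tilt_deg >= 0 & d$tilt_deg <= 180))
  expect_lt(max(abs(d$depth_nm - 0.8)), 0.2)
  expect_identical(d, syntheticSecondaryDescriptors(primary, nSub = 10,
                                                    seed = 4L))
})
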