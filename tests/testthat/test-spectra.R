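oneLine <- function(energy = 3.64, f = 0.26, kind = "absorption") {
  new("ExcitationSet",
      records = data.frame(snapshot = 1L, state = 1L, energy_eV = energy,
                           osc_strength = f),
      kind = kind)
}

test_that("the Lorentzian kernel uses delta as FWHM and is unit-normalised", {
  delta <- 0.1
  expect_equal(lorentzian(3, 3, delta), 2 / (pi * delta), tolerance = 1e-12)
  expect_equal(lorentzian(3, 3, delta), 6.3662, tolerance = 1e-4)
  # half maximum at E0 +/- delta/2
  expect_equal(lorentzian(3 + delta / 2, 3, delta),
               lorentzian(3, 3, delta) / 2, tolerance = 1e-12)
  expect_equal(lorentzian(3 - delta / 2, 3, delta),
               lorentzian(3, 3, delta) / 2, tolerance = 1e-12)
  # quadrature over +/- 500 delta integrates to ~1
  q <- integrate(lorentzian, 3 - 500 * delta, 3 + 500 * delta,
                 E0 = 3, delta = delta, subdivisions = 2000L)
  expect_lt(abs(q$value - 1), 1e-3)
  expect_error(lorentzian(3, 3, 0), "delta")
})

test_that("a one-line ensemble gives the closed-form Lorentzian peak", {
  sp <- ensembleSpectrum(oneLine(), grid = c(2, 6, 0.005), delta = 0.1)
  peak <- sp@axis[which.max(sp@intensity)]
  expect_equal(peak, 3.64, tolerance = 1e-9)
  expect_equal(max(sp@intensity), 0.26 * 2 / (pi * 0.1), tolerance = 1e-6)
})

test_that("snapshot averaging divides by distinct snapshots, not records", {
  r1 <- data.frame(snapshot = 1L, state = 1L, energy_eV = 3.2,
                   osc_strength = 0.3)
  one <- new("ExcitationSet", records = r1, kind = "absorption")
  two <- new("ExcitationSet", records = rbind(r1, transform(r1, snapshot = 2L)),
             kind = "absorption")
  s1 <- ensembleSpectrum(one, grid = c(2, 5, 0.01))
  s2 <- ensembleSpectrum(two, grid = c(2, 5, 0.01))
  expect_equal(s1@intensity, s2@intensity, tolerance = 1e-12)
  # two states within one snapshot add instead of averaging
  twoStates <- new("ExcitationSet",
                   records = rbind(r1, transform(r1, state = 2L)),
                   kind = "absorption")
  s3 <- ensembleSpectrum(twoStates, grid = c(2, 5, 0.01))
  expect_equal(s3@intensity, 2 * s1@intensity, tolerance = 1e-12)
})

test_that("spectrum integral conserves summed oscillator strength per snapshot", {
  set.seed(3)
  n <- 40L
  r <- data.frame(snapshot = rep(1:20, 2), state = rep(1:2, each = 20),
                  energy_eV = runif(n, 3, 4),
                  osc_strength = runif(n, 0.05, 0.4))
  x <- new("ExcitationSet", records = r, kind = "absorption")
  sp <- ensembleSpectrum(x, grid = c(3.5 - 50 * 0.1 - 1, 3.5 + 50 * 0.1 + 1,
                                     0.002), delta = 0.1)
  want <- sum(r$osc_strength) / 20
  expect_lt(abs(integrateSpectrum(sp) - want) / want, 0.01)
})

test_that("zero oscillator strengths give a zero spectrum", {
  x <- oneLine(f = 0)
  sp <- ensembleSpectrum(x)
  expect_true(all(sp@intensity == 0))
  expect_error(normalizeSpectrum(sp), "all-zero")
})

test_that("energy-to-wavelength conversion uses lambda = 1239.841984 / E", {
  sp <- ensembleSpectrum(oneLine(), grid = c(3, 4.5, 0.005))
  wl <- evToNm(sp)
  expect_equal(wl@unit, "nm")
  peak <- wl@axis[which.max(wl@intensity)]
  expect_equal(peak, 1239.841984 / 3.64, tolerance = 0.2)
  expect_equal(peak, 340.6, tolerance = 0.1)
  # axis is monotone increasing in wavelength (decreasing energy)
  expect_true(all(diff(wl@axis) > 0))
  # Jacobian remap conserves the integral
  withJ <- evToNm(sp, jacobian = TRUE)
  expect_equal(integrateSpectrum(withJ), integrateSpectrum(sp),
               tolerance = 0.01)
})

test_that("normalisation is scale-invariant and preserves the peak", {
  sp <- ensembleSpectrum(oneLine(), grid = c(2, 6, 0.005))
  n1 <- normalizeSpectrum(sp)
  expect_equal(max(n1@intensity), 1)
  scaled <- initialize(sp, intensity = sp@intensity * 7)
  expect_equal(normalizeSpectrum(scaled)@intensity, n1@intensity)
  expect_identical(normalizeSpectrum(n1)@intensity, n1@intensity)
  expect_equal(n1@axis[which.max(n1@intensity)],
               sp@axis[which.max(sp@intensity)])
})

test_that("band detection resolves sub-ensembles and ignores flat spectra", {
  sp <- normalizeSpectrum(ensembleSpectrum(oneLine(), grid = c(2, 6, 0.005)))
  bands <- findBands(sp)
  expect_equal(nrow(bands), 1L)
  expect_equal(bands$position, 3.64, tolerance = 1e-9)
  # two equal-weight sub-ensembles centred at 3.0 and 2.6 eV
  set.seed(5)
  r <- data.frame(snapshot = 1:200, state = 1L,
                  energy_eV = c(rnorm(100, 3.0, 0.02), rnorm(100, 2.6, 0.02)),
                  osc_strength = 0.3)
  x <- new("ExcitationSet", records = r, kind = "emission")
  two <- normalizeSpectrum(ensembleSpectrum(x, grid = c(1.5, 4, 0.005),
                                            delta = 0.1))
  bands2 <- findBands(two, prominence = 0.1)
  expect_equal(nrow(bands2), 2L)
  expect_lt(abs(bands2$position[1] - 2.6), 0.02)
  expect_lt(abs(bands2$position[2] - 3.0), 0.02)
  # all-zero spectrum: no bands
  zero <- ensembleSpectrum(oneLine(f = 0))
  expect_equal(nrow(findBands(zero)), 0L)
})

test_that("shifting every line shifts every band by the same amount", {
  set.seed(6)
  r <- data.frame(snapshot = 1:150, state = 1L,
                  energy_eV = c(rnorm(90, 3.0, 0.05), rnorm(60, 2.55, 0.05)),
                  osc_strength = 0.3)
  x <- new("ExcitationSet", records = r, kind = "emission")
  shift <- 0.4
  xs <- new("ExcitationSet",
            records = transform(r, energy_eV = energy_eV + shift),
            kind = "emission")
  b0 <- findBands(normalizeSpectrum(ensembleSpectrum(
    x, grid = c(1.5, 4.5, 0.005))), prominence = 0.1)
  b1 <- findBands(normalizeSpectrum(ensembleSpectrum(
    xs, grid = c(1.5, 4.5, 0.005))), prominence = 0.1)
  expect_equal(nrow(b0), nrow(b1))
  expect_equal(b1$position, b0$position + shift, tolerance = 0.0051)
})

test_that("the spectrum is invariant under record permutation", {
  set.seed(7)
  r <- data.frame(snapshot = 1:50, state = 1L,
                  energy_eV = runif(50, 2.5, 3.5),
                  osc_strength = runif(50, 0.1, 0.4))
  x <- new("ExcitationSet", records = r, kind = "emission")
  xp <- new("ExcitationSet", records = r[sample(50), ], kind = "emission")
  expect_equal(ensembleSpectrum(x)@intensity, ensembleSpectrum(xp)@intensity,
               tolerance = 1e-12)
})
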