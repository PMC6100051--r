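#' Unit-normalised Lorentzian line shape
#'
#' \code{L(E) = (1/pi) * (delta/2) / ((E - E0)^2 + (delta/2)^2)}, where
#' \code{delta} is the full width at half maximum (the convention used by
#' nuclear-ensemble spectrum codes for the phenomenological broadening).
#' The peak value is \code{2 / (pi * delta)} and the integral over the real
#' line is one.
#'
#' @param E energies at which to evaluate, eV.
#' @param E0 line centre, eV.
#' @param delta full width at half maximum, eV (> 0).
#' @return densities in 1/eV.
#' @export
lorentzian <- function(E, E0, delta) {
  .assertScalarNumeric(delta, "delta")
  if (delta <= 0) stop("broadening delta must be > 0")
  hw <- delta / 2
  (hw / pi) / ((E - E0)^2 + hw^2)
}

#' Synthesize a nuclear-ensemble spectrum from vertical transitions
#'
#' Semiclassical ensemble spectrum: each vertical transition contributes a
#' Lorentzian of full width \code{delta} centred at its energy, weighted by
#' its oscillator strength; contributions are summed over all states and
#' snapshots and divided by the number of distinct snapshots (so multiple
#' states within one snapshot add rather than dilute). Intensities are in
#' arbitrary units; the spectrum integrates to the mean per-snapshot total
#' oscillator strength.
#'
#' @param x an \code{ExcitationSet} (all records of one kind).
#' @param grid energy grid: \code{c(from, to, by)} in eV, or NULL for the
#'   kind-specific default (2-6 eV for absorption, 1.5-4.5 eV for
#'   emission, 0.005 eV spacing).
#' @param delta Lorentzian FWHM in eV (default 0.1, the phenomenological
#'   broadening used throughout).
#' @param emissionPrefactor apply a cubic-energy emission prefactor
#'   (\code{E^3} weighting); off by default: spectra are compared by shape.
#' @return a \code{SpectrumGrid} on an energy axis.
#' @export
ensembleSpectrum <- function(x, grid = NULL, delta = 0.1,
                             emissionPrefactor = FALSE) {
  stopifnot(is(x, "ExcitationSet"))
  r <- records(x)
  if (nrow(r) == 0L) stop("empty excitation ensemble")
  if (is.null(grid))
    grid <- if (x@kind == "absorption") c(2, 6, 0.005) else c(1.5, 4.5, 0.005)
  axis <- seq(grid[1], grid[2], by = grid[3])
  nSnap <- length(unique(r$snapshot))
  w <- r$osc_strength
  if (emissionPrefactor) w <- w * r$energy_eV^3
  intensity <- rep(0, length(axis))
  for (i in seq_len(nrow(r)))
    intensity <- intensity + w[i] * lorentzian(axis, r$energy_eV[i], delta)
  new("SpectrumGrid",
      axis = axis, intensity = intensity / nSnap, unit = "eV",
      delta = delta, kernel = "lorentzian",
      nSnapshots = as.integer(nSnap))
}

#' Re-express a spectrum on a wavelength axis
#'
#' Converts the energy axis via \code{lambda = 1239.841984 / E} (nm eV).
#' By default intensities are remapped unchanged (band shapes are compared,
#' not absolute densities); with \code{jacobian = TRUE} the spectral
#' density is transformed with the \code{|dE/dlambda|} Jacobian.
#'
#' @param x a \code{SpectrumGrid} on an energy axis.
#' @param jacobian apply the density Jacobian.
#' @return a \code{SpectrumGrid} on a wavelength axis (nm), ordered by
#'   increasing wavelength.
#' @export
evToNm <- function(x, jacobian = FALSE) {
  stopifnot(is(x, "SpectrumGrid"))
  if (x@unit != "eV") stop("spectrum is not on an energy axis")
  if (any(x@axis <= 0)) stop("energies must be positive")
  lambda <- .hc_nm_eV / x@axis
  intensity <- x@intensity
  if (jacobian) intensity <- intensity * x@axis^2 / .hc_nm_eV
  ord <- order(lambda)
  new("SpectrumGrid",
      axis = lambda[ord], intensity = intensity[ord], unit = "nm",
      delta = x@delta, kernel = x@kernel, nSnapshots = x@nSnapshots)
}

#' Normalise a spectrum to unit maximum
#'
#' @param x a \code{SpectrumGrid} with positive maximum intensity.
#' @return the spectrum scaled so its maximum intensity is one.
#' @export
normalizeSpectrum <- function(x) {
  stopifnot(is(x, "SpectrumGrid"))
  m <- max(x@intensity)
  if (m <= 0) stop("cannot normalise an all-zero spectrum")
  initialize(x, intensity = x@intensity / m)
}

#' Detect bands in a spectrum
#'
#' Local maxima of the intensity with topographic prominence at least
#' \code{prominence} (on the spectrum's own intensity scale; apply
#' \code{\link{normalizeSpectrum}} first to threshold relative to the
#' highest band). Bands are returned sorted by axis position.
#'
#' @param x a \code{SpectrumGrid}.
#' @param prominence minimum peak prominence (default 0.05).
#' @return data.frame with columns \code{position}, \code{height},
#'   \code{prominence}; zero rows if no band qualifies.
#' @export
findBands <- function(x, prominence = 0.05) {
  stopifnot(is(x, "SpectrumGrid"))
  pk <- .findPeaks(x@intensity)
  keep <- pk$prominence >= prominence
  out <- data.frame(position = x@axis[pk$index[keep]],
                    height = pk$height[keep],
                    prominence = pk$prominence[keep])
  out[order(out$position), , drop = FALSE]
}

#' Integrate a spectrum over its axis
#'
#' Trapezoidal integral of intensity over the axis, used to check the
#' nuclear-ensemble normalisation (the integral equals the summed
#' oscillator strength per snapshot when the grid spans all lines).
#'
#' @param x a \code{SpectrumGrid}.
#' @return the integral (axis units times intensity units).
#' @export
integrateSpectrum <- function(x) {
  stopifnot(is(x, "SpectrumGrid"))
  sum(diff(x@axis) * (x@intensity[-1] + x@intensity[-length(x@intensity)])) / 2
}

#' Write a spectrum as two-column text
#'
#' @param x a \code{SpectrumGrid}.
#' @param path file path.
#' @return invisibly, the path.
#' @export
writeSpectrum <- function(x, path) {
  stopifnot(is(x, "SpectrumGrid"))
  utils::write.table(
    data.frame(axis = x@axis, intensity = x@intensity),
    path, row.names = FALSE, col.names = c(x@unit, "intensity"),
    quote = FALSE)
  invisible(path)
}
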