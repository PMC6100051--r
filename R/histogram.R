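#' Build a density-normalised histogram of a geometric observable
#'
#' Bins tilt angles or penetration depths on a fixed range with a fixed bin
#' width so that the per-bin densities integrate to one. The defaults used
#' throughout the package are 5-degree bins on [0, 180] for tilt and
#' 0.05 nm bins for depth.
#'
#' @param samples numeric vector of observations (at least one).
#' @param binWidth common bin width (> 0).
#' @param range length-2 range to bin over; defaults to the sample range
#'   expanded to whole bins.
#' @return an \code{OrientationHistogram}.
#' @export
buildHistogram <- function(samples, binWidth, range = NULL) {
  if (length(samples) == 0L) stop("at least one sample is required")
  if (!all(is.finite(samples))) stop("samples must be finite")
  .assertScalarNumeric(binWidth, "binWidth")
  if (binWidth <= 0) stop("binWidth must be > 0")
  if (is.null(range)) {
    lo <- floor(min(samples) / binWidth) * binWidth
    hi <- ceiling(max(samples) / binWidth) * binWidth
    if (hi <= lo) hi <- lo + binWidth
    range <- c(lo, hi)
  }
  nb <- max(1L, as.integer(ceiling((range[2] - range[1]) / binWidth - 1e-9)))
  edges <- range[1] + (0:nb) * binWidth
  inside <- samples >= range[1] & samples <= edges[nb + 1L]
  kept <- samples[inside]
  if (!length(kept)) stop("no samples fall inside the histogram range")
  bin <- pmin(nb, pmax(1L, as.integer(
    floor((kept - range[1]) / binWidth - 1e-12) + 1L)))
  counts <- tabulate(bin, nbins = nb)
  new("OrientationHistogram",
      edges = edges,
      density = counts / (length(kept) * binWidth),
      nSamples = length(kept),
      binWidth = binWidth)
}

#' @rdname OrientationHistogram-class
#' @details \code{histogramMode} returns the centre of the bin with the
#'   highest density; ties are resolved toward the lower bin.
setMethod("histogramMode", "OrientationHistogram", function(x) {
  binCenters(x)[which.max(x@density)]
})

#' @rdname OrientationHistogram-class
#' @param minProminence smallest peak prominence to report, as a fraction
#'   of the maximum density (filters bin-count noise).
#' @details \code{localModes} returns the centres of all bins that are
#'   local maxima of the binned density with topographic prominence of at
#'   least \code{minProminence} times the maximum density, ordered by
#'   position.
setMethod("localModes", "OrientationHistogram",
          function(x, minProminence = 0.05) {
  d <- x@density
  if (length(d) == 1L) return(binCenters(x))
  pk <- .findPeaks(d)
  keep <- pk$prominence >= minProminence * max(d)
  binCenters(x)[pk$index[keep]]
})

# Local maxima of a series with topographic prominence. A peak's base on
# each side is the lowest value between it and the nearest higher point (or
# the series end); prominence is height minus the higher of the two bases.
.findPeaks <- function(y) {
  n <- length(y)
  left <- c(-Inf, y[-n])
  right <- c(y[-1], -Inf)
  idx <- which(y > left & y >= right & y > 0)
  prom <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    lmin <- y[i]
    j <- i - 1L
    while (j >= 1L && y[j] <= y[i]) { lmin <- min(lmin, y[j]); j <- j - 1L }
    rmin <- y[i]
    j <- i + 1L
    while (j <= n && y[j] <= y[i]) { rmin <- min(rmin, y[j]); j <- j + 1L }
    prom[k] <- y[i] - max(lmin, rmin)
  }
  list(index = idx, height = y[idx], prominence = prom)
}
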