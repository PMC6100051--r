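#' Construct a snapshot-selection plan
#'
#' @param window \code{c(tStart, tEnd)} trajectory-time window in ns.
#' @param n number of snapshots.
#' @param mode "equidistant" (both endpoints included) or "random"
#'   (uniform without replacement).
#' @param seed integer seed, used in random mode.
#' @return a validated \code{SamplingPlan}.
#' @export
samplingPlan <- function(window, n, mode = c("equidistant", "random"),
                         seed = 1L) {
  mode <- match.arg(mode)
  new("SamplingPlan", window = as.numeric(window), n = as.integer(n),
      mode = mode, seed = as.integer(seed))
}

# Equidistant times with both window endpoints included ((n - 1) equal
# intervals); a single snapshot falls at the window midpoint.
.equidistantTimes <- function(window, n) {
  if (n == 1L) return(mean(window))
  window[1] + (seq_len(n) - 1) * diff(window) / (n - 1)
}

# Snap requested times to the nearest stored frame; ties go to the earlier
# frame.
.nearestFrames <- function(times, frameTimes) {
  vapply(times, function(t) {
    d <- abs(frameTimes - t)
    which(d == min(d))[1]
  }, integer(1))
}

.manifestFromFrames <- function(x, frames, stage, trajectory = "primary") {
  new("EnsembleManifest",
      entries = data.frame(
        stage = stage,
        trajectory = trajectory,
        frame = as.integer(frames),
        time_ns = frameTimes(x)[frames],
        stringsAsFactors = FALSE),
      stage = stage)
}

.checkWindow <- function(x, window) {
  ft <- range(frameTimes(x))
  if (window[1] < ft[1] - 1e-9 || window[2] > ft[2] + 1e-9)
    stop(sprintf(
      "sampling window [%g, %g] ns lies outside the trajectory span [%g, %g] ns",
      window[1], window[2], ft[1], ft[2]))
}

#' Select equidistant snapshots from a trajectory
#'
#' Picks \code{n} times spaced evenly across the plan window with both
#' endpoints included, and maps each to the nearest stored frame
#' (ties toward the earlier frame). Selection is deterministic.
#'
#' @param x a \code{BilayerTrajectory}.
#' @param plan a \code{SamplingPlan} with mode "equidistant".
#' @param stage protocol stage label recorded in the manifest.
#' @return an \code{EnsembleManifest}.
#' @export
equidistantSnapshots <- function(x, plan, stage = "absorption-primary") {
  stopifnot(is(plan, "SamplingPlan"))
  if (plan@mode != "equidistant") stop("plan mode must be 'equidistant'")
  .checkWindow(x, plan@window)
  times <- .equidistantTimes(plan@window, plan@n)
  frames <- .nearestFrames(times, frameTimes(x))
  .manifestFromFrames(x, frames, stage)
}

#' Select random snapshots from a trajectory window
#'
#' Draws \code{n} distinct frames uniformly without replacement from the
#' frames whose times fall inside the window; reproducible by seed.
#'
#' @param x a \code{BilayerTrajectory}.
#' @param plan a \code{SamplingPlan} with mode "random".
#' @param stage protocol stage label recorded in the manifest.
#' @return an \code{EnsembleManifest}.
#' @export
randomSnapshots <- function(x, plan, stage = "absorption-random") {
  stopifnot(is(plan, "SamplingPlan"))
  if (plan@mode != "random") stop("plan mode must be 'random'")
  .checkWindow(x, plan@window)
  ft <- frameTimes(x)
  avail <- which(ft >= plan@window[1] - 1e-9 & ft <= plan@window[2] + 1e-9)
  if (plan@n > length(avail))
    stop(sprintf("requested %d snapshots but only %d frames in window",
                 plan@n, length(avail)))
  frames <- withSeed(plan@seed,
                     sort(sample(avail, plan@n, replace = FALSE)))
  .manifestFromFrames(x, frames, stage)
}

#' Hierarchical emission-ensemble sampling protocol
#'
#' Implements the two-level emission sampling scheme: \code{nSecondary}
#' equidistant snapshots are taken from the tail window of the primary
#' excited-state trajectory; each seeds a short secondary trajectory, from
#' which \code{nSub} equidistant times inside \code{subWindow} (relative to
#' the secondary trajectory's start) are booked. The secondary dynamics
#' itself is an external input; this function only does the book-keeping,
#' so the manifest's secondary entries carry times but no frame indices.
#'
#' With the protocol's canonical parameters -- 22 primary snapshots along
#' the last 50 ns and 10 sub-snapshots between 1 and 2 ns of each 2 ns
#' secondary trajectory -- the manifest holds 220 geometries.
#'
#' @param x the primary \code{BilayerTrajectory}.
#' @param primaryWindow \code{c(tStart, tEnd)} ns window on the primary
#'   trajectory (default: its last 50 ns).
#' @param nSecondary number of secondary-trajectory seeds (default 22).
#' @param subWindow \code{c(tStart, tEnd)} ns window within each secondary
#'   trajectory (default \code{c(1, 2)}).
#' @param nSub snapshots per secondary trajectory (default 10).
#' @return an \code{EnsembleManifest} with \code{nSecondary * nSub}
#'   secondary entries; the seeding primary frames are recorded in the
#'   manifest's \code{seedFrame} column.
#' @export
emissionProtocol <- function(x,
                             primaryWindow = NULL,
                             nSecondary = 22L,
                             subWindow = c(1, 2),
                             nSub = 10L) {
  nSecondary <- as.integer(nSecondary)
  nSub <- as.integer(nSub)
  if (nSecondary < 1L || nSub < 1L)
    stop("nSecondary and nSub must be positive")
  if (subWindow[1] > subWindow[2])
    stop("inconsistent secondary sub-window")
  if (is.null(primaryWindow)) {
    tEnd <- max(frameTimes(x))
    primaryWindow <- c(max(min(frameTimes(x)), tEnd - 50), tEnd)
  }
  .checkWindow(x, primaryWindow)
  seeds <- equidistantSnapshots(
    x, samplingPlan(primaryWindow, nSecondary, "equidistant"),
    stage = "emission-primary")
  seedFrames <- manifestEntries(seeds)$frame
  subTimes <- if (subWindow[1] == subWindow[2]) rep(subWindow[1], nSub)
  else .equidistantTimes(subWindow, nSub)
  entries <- data.frame(
    stage = "emission-secondary",
    trajectory = rep(sprintf("secondary-%02d", seq_len(nSecondary)),
                     each = nSub),
    frame = NA_integer_,
    time_ns = rep(subTimes, times = nSecondary),
    seedFrame = rep(seedFrames, each = nSub),
    seedTime_ns = rep(manifestEntries(seeds)$time_ns, each = nSub),
    stringsAsFactors = FALSE)
  new("EnsembleManifest", entries = entries, stage = "emission-secondary")
}
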