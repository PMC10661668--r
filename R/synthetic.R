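#' @include AllClasses.R
NULL

# rasterize a disk: matrix of TRUE inside (cx = column, cy = row)
.diskPixels <- function(h, w, cx, cy, r) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rows - cy)^2 + (cols - cx)^2 <= r^2
}

#' Place non-overlapping circular cells in a frame
#'
#' Rejection sampling of disk somata fully inside the frame with pairwise
#' disjoint footprints (centre distance > r_i + r_j). Deterministic under a
#' fixed seed.
#'
#' @param spec a [MovieSpec-class].
#' @param nCells number of cells.
#' @param radiusRange min/max disk radius in pixels; radii >= 3 px give areas
#'   comfortably above the 20 px area filter.
#' @param seed RNG seed (defaults to the spec's).
#' @param baselineRange per-cell baseline fluorescence F0, counts.
#' @param nuclearRange per-cell nuclear-channel intensity, counts.
#' @param maxTries rejection-sampling budget per cell.
#' @return data.frame with `id`, `cx`, `cy`, `radius`, `f0`,
#'   `nuclear_intensity`.
#' @export
sampleCells <- function(spec, nCells, radiusRange = c(3, 5), seed = spec@seed,
                        baselineRange = c(90, 130), nuclearRange = c(160, 200),
                        maxTries = 5000L) {
  stopifnot(is(spec, "MovieSpec"), nCells >= 0)
  if (nCells == 0L)
    return(data.frame(id = integer(), cx = numeric(), cy = numeric(),
                      radius = numeric(), f0 = numeric(),
                      nuclear_intensity = numeric()))
  set.seed(seed)
  h <- spec@height; w <- spec@width
  cx <- cy <- r <- numeric(0)
  tries <- 0L
  while (length(cx) < nCells) {
    tries <- tries + 1L
    if (tries > maxTries)
      stop("could not place ", nCells, " non-overlapping cells in ",
           maxTries, " tries")
    ri <- runif(1, radiusRange[1], radiusRange[2])
    xi <- runif(1, 1 + ri, w - ri)
    yi <- runif(1, 1 + ri, h - ri)
    if (all(sqrt((cx - xi)^2 + (cy - yi)^2) > r + ri + 1)) {
      cx <- c(cx, xi); cy <- c(cy, yi); r <- c(r, ri)
    }
  }
  data.frame(id = seq_len(nCells), cx = cx, cy = cy, radius = r,
             f0 = runif(nCells, baselineRange[1], baselineRange[2]),
             nuclear_intensity = runif(nCells, nuclearRange[1], nuclearRange[2]))
}

#' Simulate spike trains with network and neuron-specific events
#'
#' Synchronized network events are one shared homogeneous Poisson process;
#' each cell joins each event independently with probability
#' `networkParticipation`. Neuron-specific events are an independent Poisson
#' process per cell. The per-cell train is the merged union (duplicate frames
#' collapsed), in frame indices.
#'
#' @param cells cell table from [sampleCells()].
#' @param activity an [ActivityModel-class].
#' @param spec a [MovieSpec-class].
#' @param seed RNG seed.
#' @return list (one integer vector of spike frames per cell, 1-based).
#' @export
simulateSpikes <- function(cells, activity, spec, seed = spec@seed) {
  stopifnot(is(activity, "ActivityModel"), is(spec, "MovieSpec"))
  validObject(activity)
  set.seed(seed)
  nC <- nrow(cells)
  durMin <- spec@nFrames * spec@frameInterval / 60
  toFrame <- function(tMin) pmin(spec@nFrames,
                                 1L + as.integer(floor(tMin * 60 / spec@frameInterval)))
  nNet <- rpois(1, activity@networkEventRate * durMin)
  netFrames <- toFrame(sort(runif(nNet, 0, durMin)))
  lapply(seq_len(nC), function(k) {
    join <- if (nNet > 0) runif(nNet) < activity@networkParticipation else logical(0)
    nPriv <- rpois(1, activity@privateRate * durMin)
    priv <- toFrame(runif(nPriv, 0, durMin))
    sort(unique(c(netFrames[join], priv)))
  })
}

#' Render a two-channel calcium movie with ground truth
#'
#' Functional channel, per pixel of cell k:
#' `F(t) = trend(t) * F0 * (1 + sum_s A * exp(-(t - t_s)/tau) * [t >= t_s]) + eps`,
#' with instantaneous rise, exponential decay `tau`, multiplicative
#' exponential bleaching trend and additive Gaussian read noise, rounded and
#' clipped to the bit depth. Outside cells the functional baseline is a dim
#' background. The nuclear channel is static disks of each cell's nuclear
#' intensity over the same background, plus noise.
#'
#' @param cells cell table from [sampleCells()].
#' @param spikes spike-frame list from [simulateSpikes()].
#' @param activity an [ActivityModel-class] (kernel parameters).
#' @param nuisance a [NuisanceModel-class]; `bleachTau = NA` defaults to 10x
#'   the movie duration.
#' @param spec a [MovieSpec-class].
#' @param seed RNG seed (noise only; layout and spikes are already fixed).
#' @param background background intensity, counts.
#' @return a [CalciumMovie-class] with ground truth attached.
#' @export
renderMovie <- function(cells, spikes, activity, nuisance, spec,
                        seed = spec@seed, background = 20) {
  stopifnot(is(nuisance, "NuisanceModel"), is(spec, "MovieSpec"))
  validObject(nuisance); validObject(spec)
  set.seed(seed)
  h <- spec@height; w <- spec@width; nT <- spec@nFrames
  dt <- spec@frameInterval
  maxCount <- 2^spec@bitDepth - 1
  bleachTau <- nuisance@bleachTau
  if (is.na(bleachTau)) bleachTau <- 10 * nT * dt
  tSec <- (seq_len(nT) - 1) * dt
  trend <- exp(-tSec / bleachTau)

  mask <- matrix(0L, h, w)
  for (k in seq_len(nrow(cells))) {
    d <- .diskPixels(h, w, cells$cx[k], cells$cy[k], cells$radius[k])
    mask[d] <- k
  }

  # baseline images
  baseF <- matrix(background, h, w)
  baseN <- matrix(background, h, w)
  for (k in seq_len(nrow(cells))) {
    baseF[mask == k] <- cells$f0[k]
    baseN[mask == k] <- cells$nuclear_intensity[k]
  }

  # per-cell transient time courses: 1 + sum of decaying kernels
  course <- matrix(1, nrow(cells), nT)
  if (nrow(cells))
    for (k in seq_len(nrow(cells))) {
      for (fs in spikes[[k]]) {
        idx <- fs:nT
        course[k, idx] <- course[k, idx] +
          activity@transientAmplitude * exp(-(tSec[idx] - tSec[fs]) / activity@decayTau)
      }
    }

  fun <- array(rep(baseF, nT), dim = c(h, w, nT))
  fun <- sweep(fun, 3, trend, `*`)
  for (k in seq_len(nrow(cells))) {
    px <- which(mask == k)
    if (!length(px)) next
    # outer product: pixels x time modulation
    fun[rep(px, nT) + rep((seq_len(nT) - 1L) * h * w, each = length(px))] <-
      as.vector(outer(baseF[px], course[k, ] * trend))
  }
  clipWarn <- FALSE
  if (nuisance@shotNoise) fun[] <- rpois(length(fun), pmax(fun, 0))
  if (nuisance@noiseSigma > 0)
    fun <- fun + rnorm(length(fun), 0, nuisance@noiseSigma)
  nClip <- sum(fun[rep(mask > 0, nT)] > maxCount)
  if (nClip > 0.01 * sum(mask > 0) * nT) {
    warning("transient amplitude causes systematic clipping (",
            signif(100 * nClip / (sum(mask > 0) * nT), 2), "% of in-cell samples)")
    clipWarn <- TRUE
  }
  fun <- array(as.integer(pmin(pmax(round(fun), 0), maxCount)), dim = c(h, w, nT))

  nuc <- array(rep(baseN, nT), dim = c(h, w, nT))
  if (nuisance@noiseSigma > 0)
    nuc <- nuc + rnorm(length(nuc), 0, nuisance@noiseSigma)
  nuc <- array(as.integer(pmin(pmax(round(nuc), 0), maxCount)), dim = c(h, w, nT))

  new("CalciumMovie", functional = fun, nuclear = nuc,
      frameInterval = dt, bitDepth = spec@bitDepth,
      groundTruth = list(cells = cells, spikes = spikes, mask = mask,
                         clipped = clipWarn))
}

#' One-call seeded movie simulation
#'
#' Samples cells, simulates spike trains and renders both channels with
#' deterministic sub-seeds derived from `seed`, so one integer reproduces the
#' whole movie.
#'
#' @param spec a [MovieSpec-class].
#' @param nCells number of cells.
#' @param activity an [ActivityModel-class].
#' @param nuisance a [NuisanceModel-class].
#' @param seed master seed.
#' @param ... passed to [sampleCells()].
#' @return a [CalciumMovie-class].
#' @export
simulateCalciumMovie <- function(spec = MovieSpec(), nCells = 30,
                                 activity = ActivityModel(),
                                 nuisance = NuisanceModel(),
                                 seed = spec@seed, ...) {
  cells <- sampleCells(spec, nCells, seed = seed, ...)
  spikes <- simulateSpikes(cells, activity, spec, seed = seed + 1L)
  renderMovie(cells, spikes, activity, nuisance, spec, seed = seed + 2L)
}
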