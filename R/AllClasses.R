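#' @import methods
#' @importFrom stats median sd var qt pt qt qnorm quantile rnorm rpois runif
#'   rbinom setNames
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.posScalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0

#' Rectangular microchannel geometry
#'
#' Geometry of one electrolyte-filled channel section. The cross-section
#' `A = w * h` determines both its resistance (Pouillet's law
#' `R = L / (sigma * w * h)`) and the field a current produces in it
#' (`E = i / (sigma * w * h)`).
#'
#' @slot length channel length along the current path, metres.
#' @slot width channel width, metres.
#' @slot height channel height (chamber thickness), metres.
#' @slot label section label, e.g. `"s1"`.
#' @export
setClass("ChannelGeometry",
  representation(length = "numeric", width = "numeric", height = "numeric",
                 label = "character"),
  prototype(label = NA_character_))

setValidity("ChannelGeometry", function(object) {
  for (s in c("length", "width", "height"))
    if (!.posScalar(slot(object, s)))
      return(sprintf("'%s' must be a single positive finite number", s))
  TRUE
})

#' @rdname ChannelGeometry-class
#' @param length,width,height channel dimensions in metres.
#' @param label section label.
#' @export
ChannelGeometry <- function(length, width, height, label = NA_character_)
  new("ChannelGeometry", length = length, width = width, height = height,
      label = as.character(label))

#' Electrolyte filling the chamber
#'
#' @slot conductivity ionic conductivity sigma, S/m. Culture media and 1x PBS
#'   are close to 1.5 S/m.
#' @export
setClass("Electrolyte", representation(conductivity = "numeric"))

setValidity("Electrolyte", function(object) {
  if (!.posScalar(object@conductivity)) "conductivity must be > 0" else TRUE
})

#' @rdname Electrolyte-class
#' @param conductivity sigma in S/m.
#' @export
Electrolyte <- function(conductivity) new("Electrolyte", conductivity = conductivity)

#' Disk electrode specification
#'
#' Capacitance and usable voltage window are optional (`NA` when unknown);
#' they parameterize the capacitive discharge window `t = C * dV / i`.
#'
#' @slot diameter disk diameter, metres.
#' @slot capacitance interfacial capacitance C, farads, or `NA`.
#' @slot voltageWindow usable voltage window dV, volts, or `NA`.
#' @export
setClass("ElectrodeSpec",
  representation(diameter = "numeric", capacitance = "numeric",
                 voltageWindow = "numeric"),
  prototype(capacitance = NA_real_, voltageWindow = NA_real_))

setValidity("ElectrodeSpec", function(object) {
  if (!.posScalar(object@diameter)) return("diameter must be > 0")
  if (!is.na(object@capacitance) && object@capacitance <= 0)
    return("capacitance must be > 0 when given")
  if (!is.na(object@voltageWindow) && object@voltageWindow <= 0)
    return("voltageWindow must be > 0 when given")
  TRUE
})

#' @rdname ElectrodeSpec-class
#' @param diameter disk diameter, metres.
#' @param capacitance farads (optional).
#' @param voltageWindow volts (optional).
#' @export
ElectrodeSpec <- function(diameter, capacitance = NA_real_,
                          voltageWindow = NA_real_)
  new("ElectrodeSpec", diameter = diameter, capacitance = capacitance,
      voltageWindow = voltageWindow)

#' Stimulation protocol (DC or pulsed constant current)
#'
#' @slot mode `"dc"` or `"pulsed"`.
#' @slot current drive current i, amperes.
#' @slot duration total on-time for DC, seconds.
#' @slot pulseOn,pulseOff per-pulse on/off times, seconds (pulsed mode).
#' @slot nPulses number of on/off cycles (pulsed mode).
#' @export
setClass("StimulationProtocol",
  representation(mode = "character", current = "numeric", duration = "numeric",
                 pulseOn = "numeric", pulseOff = "numeric", nPulses = "numeric"),
  prototype(duration = NA_real_, pulseOn = NA_real_, pulseOff = NA_real_,
            nPulses = NA_real_))

setValidity("StimulationProtocol", function(object) {
  if (!object@mode %in% c("dc", "pulsed")) return("mode must be 'dc' or 'pulsed'")
  if (!.posScalar(object@current)) return("current must be > 0")
  if (object@mode == "dc") {
    if (!is.numeric(object@duration) || is.na(object@duration) ||
        object@duration < 0) return("dc mode needs duration >= 0")
  } else {
    if (is.na(object@pulseOn) || object@pulseOn < 0) return("pulseOn must be >= 0")
    if (is.na(object@pulseOff) || object@pulseOff < 0) return("pulseOff must be >= 0")
    if (is.na(object@nPulses) || object@nPulses < 0 ||
        object@nPulses != round(object@nPulses)) return("nPulses must be a count >= 0")
  }
  TRUE
})

#' @rdname StimulationProtocol-class
#' @param current amperes.
#' @param duration seconds (DC).
#' @param pulseOn,pulseOff seconds per pulse (pulsed).
#' @param nPulses number of pulses.
#' @export
dcProtocol <- function(current, duration)
  new("StimulationProtocol", mode = "dc", current = current, duration = duration)

#' @rdname StimulationProtocol-class
#' @export
pulsedProtocol <- function(current, pulseOn, pulseOff, nPulses)
  new("StimulationProtocol", mode = "pulsed", current = current,
      pulseOn = pulseOn, pulseOff = pulseOff, nPulses = nPulses)

#' Resistor-network model of the fluidic chamber
#'
#' Directed multigraph of resistive channel segments with one ideal current
#' source between two terminal nodes. Edges carrying a [ChannelGeometry-class]
#' are stimulation sections whose field is reported by [sectionFields()].
#'
#' @slot edges data.frame with columns `from`, `to`, `resistance` (ohms) and
#'   `label`; one row per resistor, parallel edges allowed.
#' @slot geometries named list of [ChannelGeometry-class] objects, keyed by
#'   edge label, for edges that are physical channel sections.
#' @slot source list with `from`, `to`, `current` (amperes): the current
#'   enters at `from` and leaves at `to`.
#' @export
setClass("ResistorNetwork",
  representation(edges = "data.frame", geometries = "list", source = "list"))

setValidity("ResistorNetwork", function(object) {
  ed <- object@edges
  need <- c("from", "to", "resistance", "label")
  if (!all(need %in% names(ed))) return("edges needs from/to/resistance/label")
  if (nrow(ed) == 0L) return("network has no edges")
  if (any(!is.finite(ed$resistance)) || any(ed$resistance <= 0))
    return("all resistances must be positive and finite")
  src <- object@source
  if (!all(c("from", "to", "current") %in% names(src)))
    return("source needs from/to/current")
  nodes <- unique(c(ed$from, ed$to))
  if (!all(c(src$from, src$to) %in% nodes))
    return("source terminals must be network nodes")
  if (!is.finite(src$current)) return("source current must be finite")
  gl <- names(object@geometries)
  if (length(object@geometries) && !all(gl %in% ed$label))
    return("geometry labels must match edge labels")
  if (!.nodesConnected(ed, src$from, src$to))
    return("source terminals are not connected through the network")
  TRUE
})

# undirected reachability between the two source terminals
.nodesConnected <- function(edges, a, b) {
  if (a == b) return(TRUE)
  adj <- split(c(edges$to, edges$from), c(edges$from, edges$to))
  seen <- a; frontier <- a
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    if (b %in% nxt) return(TRUE)
    seen <- c(seen, nxt); frontier <- nxt
  }
  FALSE
}

#' Two-column sampled trace (voltage excursion or cyclic voltammogram)
#'
#' @slot x strictly increasing abscissa (seconds for excursions, volts for CV).
#' @slot y ordinate (volts for excursions, amperes for CV).
#' @export
setClass("SampledTrace", representation(x = "numeric", y = "numeric"))

setValidity("SampledTrace", function(object) {
  if (length(object@x) != length(object@y)) return("x and y lengths differ")
  if (length(object@x) < 2L) return("need at least 2 samples")
  if (any(!is.finite(object@x)) || any(!is.finite(object@y)))
    return("samples must be finite")
  if (any(diff(object@x) <= 0)) return("x must be strictly increasing")
  TRUE
})

#' @rdname SampledTrace-class
#' @param x,y numeric vectors of equal length; `x` strictly increasing.
#' @export
SampledTrace <- function(x, y) new("SampledTrace", x = as.numeric(x), y = as.numeric(y))

#' Movie acquisition specification
#'
#' Defaults mirror a 128 x 128 px field recorded for 2 min at 120 ms frame
#' intervals (1000 frames) on an 8-bit intensity scale.
#'
#' @slot height,width frame size in pixels.
#' @slot nFrames number of frames.
#' @slot frameInterval seconds between frames.
#' @slot bitDepth intensity bit depth (8 gives counts in 0..255).
#' @slot seed default RNG seed for simulation helpers.
#' @export
setClass("MovieSpec",
  representation(height = "integer", width = "integer", nFrames = "integer",
                 frameInterval = "numeric", bitDepth = "integer",
                 seed = "integer"))

setValidity("MovieSpec", function(object) {
  if (object@height < 8L || object@width < 8L) return("frame too small")
  if (object@nFrames < 2L) return("need nFrames >= 2")
  if (!.posScalar(object@frameInterval)) return("frameInterval must be > 0")
  if (!object@bitDepth %in% c(8L, 12L, 16L)) return("bitDepth must be 8, 12 or 16")
  TRUE
})

#' @rdname MovieSpec-class
#' @param height,width,nFrames,frameInterval,bitDepth,seed see slots.
#' @export
MovieSpec <- function(height = 128, width = 128, nFrames = 1000,
                      frameInterval = 0.120, bitDepth = 8, seed = 1)
  new("MovieSpec", height = as.integer(height), width = as.integer(width),
      nFrames = as.integer(nFrames), frameInterval = frameInterval,
      bitDepth = as.integer(bitDepth), seed = as.integer(seed))

#' Calcium transient activity model
#'
#' Spike trains combine network-wide synchronized events (one shared Poisson
#' process; each cell joins each event with probability
#' `networkParticipation`) and neuron-specific events (independent Poisson per
#' cell). Transients rise instantaneously and decay exponentially, a GCaMP6f
#' style kernel.
#'
#' @slot networkEventRate synchronized events per minute.
#' @slot networkParticipation probability a cell joins a network event.
#' @slot privateRate neuron-specific spikes per minute per cell.
#' @slot transientAmplitude peak dF/F of one transient (fraction of baseline).
#' @slot decayTau decay time constant, seconds.
#' @export
setClass("ActivityModel",
  representation(networkEventRate = "numeric", networkParticipation = "numeric",
                 privateRate = "numeric", transientAmplitude = "numeric",
                 decayTau = "numeric"))

setValidity("ActivityModel", function(object) {
  if (object@networkEventRate < 0 || object@privateRate < 0)
    return("rates must be >= 0")
  if (object@networkParticipation < 0 || object@networkParticipation > 1)
    return("networkParticipation must lie in [0, 1]")
  if (object@transientAmplitude < 0) return("transientAmplitude must be >= 0")
  if (!.posScalar(object@decayTau)) return("decayTau must be > 0")
  TRUE
})

#' @rdname ActivityModel-class
#' @param networkEventRate,networkParticipation,privateRate,transientAmplitude,decayTau see slots.
#' @export
ActivityModel <- function(networkEventRate = 6, networkParticipation = 0.8,
                          privateRate = 2, transientAmplitude = 0.3,
                          decayTau = 0.4)
  new("ActivityModel", networkEventRate = networkEventRate,
      networkParticipation = networkParticipation, privateRate = privateRate,
      transientAmplitude = transientAmplitude, decayTau = decayTau)

#' Slow-trend and noise model for rendered movies
#'
#' @slot bleachTau time constant of the multiplicative exponential bleaching
#'   trend, seconds; `Inf` disables the trend, `NA` (the default) resolves at
#'   render time to 10x the movie duration (a mild trend).
#' @slot noiseSigma SD of additive Gaussian read noise, counts.
#' @slot shotNoise replace the deterministic signal by a Poisson draw of the
#'   same mean before adding read noise.
#' @export
setClass("NuisanceModel",
  representation(bleachTau = "numeric", noiseSigma = "numeric",
                 shotNoise = "logical"))

setValidity("NuisanceModel", function(object) {
  if (!is.na(object@bleachTau) && object@bleachTau <= 0)
    return("bleachTau must be > 0 (Inf to disable, NA for the default)")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  TRUE
})

#' @rdname NuisanceModel-class
#' @param bleachTau,noiseSigma,shotNoise see slots.
#' @export
NuisanceModel <- function(bleachTau = NA_real_, noiseSigma = 5, shotNoise = FALSE)
  new("NuisanceModel", bleachTau = bleachTau, noiseSigma = noiseSigma,
      shotNoise = isTRUE(shotNoise))

#' Two-channel calcium movie with optional ground truth
#'
#' Frames are stored as `height x width x frames` integer arrays in counts.
#' Simulated movies carry their ground truth: the cell table, per-cell spike
#' frames and the pixel-exact label mask used for rendering.
#'
#' @slot functional calcium-indicator channel, H x W x T array of counts.
#' @slot nuclear static nuclear channel, same shape.
#' @slot frameInterval seconds between frames.
#' @slot bitDepth intensity bit depth.
#' @slot groundTruth list with `cells` (data.frame), `spikes` (list of integer
#'   frame vectors) and `mask` (integer matrix), or empty for real data.
#' @export
setClass("CalciumMovie",
  representation(functional = "array", nuclear = "array",
                 frameInterval = "numeric", bitDepth = "integer",
                 groundTruth = "list"),
  prototype(groundTruth = list()))

setValidity("CalciumMovie", function(object) {
  df <- dim(object@functional); dn <- dim(object@nuclear)
  if (length(df) != 3L) return("functional must be H x W x T")
  if (!identical(df, dn)) return("channel dimensions differ")
  if (!.posScalar(object@frameInterval)) return("frameInterval must be > 0")
  TRUE
})

#' Cell-detection parameters
#'
#' Defaults follow the nuclear-channel detection chain: median blur (3 px),
#' background estimation by a 32 px grayscale opening which is subtracted,
#' contour sharpening by a 2 px opening, binary threshold at 100 counts,
#' connected components, and rejection of components with area <= 20 px.
#'
#' @slot medianBlurSize odd median-filter window, pixels.
#' @slot backgroundKernel opening footprint for background estimation, pixels.
#' @slot sharpenKernel opening footprint for contour sharpening, pixels.
#' @slot threshold binary threshold, counts.
#' @slot minArea components with area <= minArea are dropped (strict).
#' @slot connectivity 4 or 8.
#' @slot kernelShape `"square"` or `"disc"` structuring elements.
#' @export
setClass("DetectionParams",
  representation(medianBlurSize = "integer", backgroundKernel = "integer",
                 sharpenKernel = "integer", threshold = "numeric",
                 minArea = "integer", connectivity = "integer",
                 kernelShape = "character"))

setValidity("DetectionParams", function(object) {
  if (object@medianBlurSize < 1L || object@medianBlurSize %% 2L == 0L)
    return("medianBlurSize must be odd and >= 1")
  if (object@backgroundKernel < 1L || object@sharpenKernel < 1L)
    return("kernels must be >= 1")
  if (object@threshold < 0) return("threshold must be >= 0")
  if (object@minArea < 0L) return("minArea must be >= 0")
  if (!object@connectivity %in% c(4L, 8L)) return("connectivity must be 4 or 8")
  if (!object@kernelShape %in% c("square", "disc"))
    return("kernelShape must be 'square' or 'disc'")
  TRUE
})

#' @rdname DetectionParams-class
#' @param medianBlurSize,backgroundKernel,sharpenKernel,threshold,minArea,connectivity,kernelShape see slots.
#' @export
DetectionParams <- function(medianBlurSize = 3, backgroundKernel = 32,
                            sharpenKernel = 2, threshold = 100, minArea = 20,
                            connectivity = 8, kernelShape = "square")
  new("DetectionParams", medianBlurSize = as.integer(medianBlurSize),
      backgroundKernel = as.integer(backgroundKernel),
      sharpenKernel = as.integer(sharpenKernel), threshold = threshold,
      minArea = as.integer(minArea), connectivity = as.integer(connectivity),
      kernelShape = kernelShape)

#' Labeled cell mask
#'
#' Integer image with 0 background and labels 1..K in raster order of each
#' component's first pixel, plus the per-ROI summary table.
#'
#' @slot mask H x W integer matrix.
#' @slot table data.frame with `label`, `area`, `centroid_x` (column),
#'   `centroid_y` (row).
#' @export
setClass("LabelMask",
  representation(mask = "matrix", table = "data.frame"))

setValidity("LabelMask", function(object) {
  labs <- sort(unique(as.integer(object@mask[object@mask > 0])))
  k <- nrow(object@table)
  if (length(labs) && !identical(labs, seq_len(max(labs))))
    return("labels must be contiguous 1..K")
  if (length(labs) != k) return("table rows must match label count")
  if (k && !identical(sort(object@table$label), labs))
    return("table labels must match mask labels")
  TRUE
})

#' Trace-processing parameters
#'
#' @slot rollingWindow rolling-median window for detrending, frames.
#' @slot spikeK SD multiplier of the spike threshold (mean + k * SD).
#' @slot minSeparation supra-threshold runs separated by fewer than this many
#'   frames are merged into one event.
#' @export
setClass("TraceParams",
  representation(rollingWindow = "integer", spikeK = "numeric",
                 minSeparation = "integer"))

setValidity("TraceParams", function(object) {
  if (object@rollingWindow < 2L) return("rollingWindow must be >= 2")
  if (object@spikeK <= 0) return("spikeK must be > 0")
  if (object@minSeparation < 0L) return("minSeparation must be >= 0")
  TRUE
})

#' @rdname TraceParams-class
#' @param rollingWindow,spikeK,minSeparation see slots.
#' @export
TraceParams <- function(rollingWindow = 20, spikeK = 3, minSeparation = 2)
  new("TraceParams", rollingWindow = as.integer(rollingWindow), spikeK = spikeK,
      minSeparation = as.integer(minSeparation))

#' Per-ROI fluorescence traces
#'
#' A [SummarizedExperiment-class] with ROIs as rows and frames as columns.
#' Assay `"raw"` holds the spatially averaged fluorescence; after
#' [detrendNormalize()] assays `"trend"` (centered rolling median) and
#' `"dff"` (dF/F0) are added. `rowData` carries the ROI table, `colData` the
#' frame index and time in seconds.
#'
#' @export
setClass("TraceSet", contains = "SummarizedExperiment")

#' Called calcium spikes
#'
#' @slot calls data.frame with `roi`, `frame`, `time_s` (one row per event,
#'   frame is the within-run peak).
#' @slot thresholds named per-ROI dF/F thresholds actually used.
#' @slot duration trace duration, seconds.
#' @slot params the [TraceParams-class] used.
#' @export
setClass("SpikeCalls",
  representation(calls = "data.frame", thresholds = "numeric",
                 duration = "numeric", params = "TraceParams"))

setValidity("SpikeCalls", function(object) {
  if (!all(c("roi", "frame", "time_s") %in% names(object@calls)))
    return("calls needs roi/frame/time_s")
  if (!.posScalar(object@duration)) return("duration must be > 0")
  ok <- vapply(split(object@calls$frame, object@calls$roi),
               function(f) all(diff(f) > 0), logical(1))
  if (length(ok) && !all(ok)) return("frames must be strictly increasing per roi")
  TRUE
})
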