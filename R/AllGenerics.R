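#' @include AllClasses.R
NULL

#' Cross-sectional area of a channel
#'
#' @param x a [ChannelGeometry-class].
#' @return area `w * h` in square metres.
#' @export
setGeneric("crossSection", function(x) standardGeneric("crossSection"))

#' @rdname crossSection
#' @export
setMethod("crossSection", "ChannelGeometry", function(x) x@width * x@height)

#' Accessors for movies, masks, traces and spike calls
#'
#' @param x the object.
#' @param channel `"functional"` or `"nuclear"`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("movieChannel", function(x, channel = c("functional", "nuclear"))
  standardGeneric("movieChannel"))

#' @rdname accessors
#' @export
setMethod("movieChannel", "CalciumMovie", function(x, channel = c("functional", "nuclear")) {
  channel <- match.arg(channel)
  slot(x, channel)
})

#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname accessors
#' @export
setMethod("frameInterval", "CalciumMovie", function(x) x@frameInterval)

#' @rdname accessors
#' @export
setMethod("frameInterval", "TraceSet", function(x) S4Vectors::metadata(x)$frameInterval)

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setMethod("groundTruth", "CalciumMovie", function(x) x@groundTruth)

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setMethod("nFrames", "CalciumMovie", function(x) dim(x@functional)[3L])

#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname accessors
#' @export
setMethod("labelMatrix", "LabelMask", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("roiTable", function(x) standardGeneric("roiTable"))

#' @rdname accessors
#' @export
setMethod("roiTable", "LabelMask", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname accessors
#' @export
setMethod("nCells", "LabelMask", function(x) nrow(x@table))

#' @rdname accessors
#' @export
setGeneric("spikeFrames", function(x) standardGeneric("spikeFrames"))

#' @rdname accessors
#' @export
setMethod("spikeFrames", "SpikeCalls", function(x) x@calls)

#' @rdname accessors
#' @export
setGeneric("spikeThresholds", function(x) standardGeneric("spikeThresholds"))

#' @rdname accessors
#' @export
setMethod("spikeThresholds", "SpikeCalls", function(x) x@thresholds)

setMethod("show", "ChannelGeometry", function(object) {
  cat(sprintf("ChannelGeometry '%s': L = %g mm, w = %g mm, h = %g mm (A = %g mm^2)\n",
              object@label, object@length * 1e3, object@width * 1e3,
              object@height * 1e3, crossSection(object) * 1e6))
})

setMethod("show", "ResistorNetwork", function(object) {
  cat(sprintf("ResistorNetwork: %d nodes, %d edges, source %s -> %s (%g uA)\n",
              length(unique(c(object@edges$from, object@edges$to))),
              nrow(object@edges), object@source$from, object@source$to,
              object@source$current * 1e6))
  ng <- names(object@geometries)
  if (length(ng)) cat("  sections:", paste(ng, collapse = ", "), "\n")
})

setMethod("show", "CalciumMovie", function(object) {
  d <- dim(object@functional)
  cat(sprintf("CalciumMovie: %d x %d px, %d frames @ %g ms (%.1f s), %d-bit\n",
              d[1], d[2], d[3], object@frameInterval * 1e3,
              d[3] * object@frameInterval, object@bitDepth))
  if (length(object@groundTruth))
    cat(sprintf("  ground truth: %d cells\n", nrow(object@groundTruth$cells)))
})

setMethod("show", "LabelMask", function(object) {
  cat(sprintf("LabelMask: %d x %d px, %d cells\n",
              nrow(object@mask), ncol(object@mask), nCells(object)))
})

setMethod("show", "SpikeCalls", function(object) {
  cat(sprintf("SpikeCalls: %d events across %d ROIs over %.1f s\n",
              nrow(object@calls), length(object@thresholds), object@duration))
})
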