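#' @include AllClasses.R
NULL

#' Centered rolling median with shrinking edge windows
#'
#' For window `w` the window at index `t` spans
#' `[t - floor(w/2), t + ceiling(w/2) - 1]`, clipped to the trace: full-width
#' and centered in the interior, shrinking towards the edges so the trend is
#' defined at every frame.
#'
#' @param x numeric vector.
#' @param w window width in samples (>= 2).
#' @return numeric vector of the same length.
#' @export
rollingMedian <- function(x, w) {
  n <- length(x)
  if (w < 2L) stop("window must be >= 2")
  lo <- pmax(seq_len(n) - w %/% 2L, 1L)
  hi <- pmin(seq_len(n) + (w - w %/% 2L) - 1L, n)
  vapply(seq_len(n), function(t) median(x[lo[t]:hi[t]]), numeric(1))
}

#' Extract per-ROI fluorescence traces
#'
#' `F_k(t)` is the spatial mean over the pixels of label `k` in every frame.
#'
#' @param x H x W x T array (functional channel) or a [CalciumMovie-class].
#' @param mask a [LabelMask-class] (or integer matrix) matching the frame
#'   shape.
#' @param frameInterval seconds between frames; taken from the movie when `x`
#'   is a [CalciumMovie-class].
#' @return a [TraceSet-class] with assay `"raw"` (ROIs x frames).
#' @export
extractTraces <- function(x, mask, frameInterval = NULL) {
  if (is(x, "CalciumMovie")) {
    if (is.null(frameInterval)) frameInterval <- x@frameInterval
    x <- movieChannel(x, "functional")
  }
  if (is.null(frameInterval)) stop("frameInterval required for a bare array")
  roi <- if (is(mask, "LabelMask")) roiTable(mask) else .maskTable(mask)
  m <- if (is(mask, "LabelMask")) labelMatrix(mask) else mask
  d <- dim(x)
  if (!identical(dim(m), d[1:2])) stop("mask shape does not match frames")
  if (nrow(roi) == 0L) stop("mask has no labeled ROIs")
  flat <- matrix(x, d[1] * d[2], d[3])
  px <- which(m > 0)
  sums <- rowsum(flat[px, , drop = FALSE], group = m[px])
  raw <- sums / roi$area[match(as.integer(rownames(sums)), roi$label)]
  rownames(raw) <- paste0("roi", rownames(sums))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(raw = raw),
    rowData = S4Vectors::DataFrame(roi, row.names = rownames(raw)),
    colData = S4Vectors::DataFrame(
      frame = seq_len(d[3]),
      time_s = (seq_len(d[3]) - 1) * frameInterval))
  S4Vectors::metadata(se)$frameInterval <- frameInterval
  as(se, "TraceSet")
}

#' Detrend traces and normalize to dF/F0
#'
#' The slow trend of each raw trace is its centered rolling median
#' ([rollingMedian()], default window 20 frames). The detrended trace is
#' normalized by the mean of the trend, giving a dimensionless dF/F0:
#' `dff(t) = (F(t) - trend(t)) / mean(trend)`.
#'
#' @param ts a [TraceSet-class] with assay `"raw"`.
#' @param params a [TraceParams-class].
#' @return the [TraceSet-class] with assays `"trend"` and `"dff"` added.
#' @export
detrendNormalize <- function(ts, params = TraceParams()) {
  stopifnot(is(ts, "TraceSet"), is(params, "TraceParams"))
  validObject(params)
  raw <- SummarizedExperiment::assay(ts, "raw")
  if (ncol(raw) <= params@rollingWindow)
    stop("trace shorter than the rolling window")
  trend <- t(apply(raw, 1L, rollingMedian, w = params@rollingWindow))
  f0 <- rowMeans(trend)
  if (any(f0 <= 0))
    stop("non-positive trend mean for ROI(s): ",
         paste(rownames(raw)[f0 <= 0], collapse = ", "))
  dff <- (raw - trend) / f0
  SummarizedExperiment::assays(ts)[["trend"]] <- trend
  SummarizedExperiment::assays(ts)[["dff"]] <- dff
  S4Vectors::metadata(ts)$traceParams <- params
  ts
}

# one event per supra-threshold run (reported at the run's peak); runs
# separated by fewer than minSep below-threshold frames are merged
.callSpikes <- function(dff, theta, minSep) {
  above <- dff > theta
  if (!any(above)) return(integer(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  if (nrow(runs) > 1L && minSep > 0L) {
    merged <- runs[1L, , drop = FALSE]
    for (j in 2:nrow(runs)) {
      gap <- runs[j, 1L] - merged[nrow(merged), 2L] - 1L
      if (gap < minSep) merged[nrow(merged), 2L] <- runs[j, 2L]
      else merged <- rbind(merged, runs[j, ])
    }
    runs <- merged
  }
  vapply(seq_len(nrow(runs)), function(j) {
    seg <- runs[j, 1L]:runs[j, 2L]
    seg[which.max(dff[seg])]
  }, integer(1))
}

#' Call calcium spikes on dF/F0 traces
#'
#' The per-ROI threshold is `mean(dff) + k * SD(dff)` computed over the full
#' processed trace. Each contiguous supra-threshold run yields one event at
#' its peak frame; runs closer than `minSeparation` frames are merged. A
#' zero-variance trace yields no calls.
#'
#' @param ts a [TraceSet-class] after [detrendNormalize()].
#' @param params a [TraceParams-class].
#' @return a [SpikeCalls-class].
#' @export
detectSpikes <- function(ts, params = TraceParams()) {
  stopifnot(is(ts, "TraceSet"), is(params, "TraceParams"))
  if (!"dff" %in% SummarizedExperiment::assayNames(ts))
    stop("run detrendNormalize() first")
  dff <- SummarizedExperiment::assay(ts, "dff")
  if (any(!is.finite(dff))) stop("dff contains non-finite values")
  dt <- frameInterval(ts)
  calls <- list(); thr <- setNames(numeric(nrow(dff)), rownames(dff))
  for (k in seq_len(nrow(dff))) {
    v <- dff[k, ]
    s <- sd(v)
    theta <- mean(v) + params@spikeK * s
    thr[k] <- theta
    frames <- if (s == 0) integer(0)
              else .callSpikes(v, theta, params@minSeparation)
    if (length(frames))
      calls[[length(calls) + 1L]] <- data.frame(
        roi = rownames(dff)[k], frame = frames, time_s = (frames - 1) * dt)
  }
  calls <- if (length(calls)) do.call(rbind, calls)
           else data.frame(roi = character(), frame = integer(),
                           time_s = numeric())
  new("SpikeCalls", calls = calls, thresholds = thr,
      duration = ncol(dff) * dt, params = params)
}

#' Per-ROI spike rates
#'
#' @param x a [SpikeCalls-class].
#' @return data.frame with `roi`, `n_spikes`, `rate_per_min`.
#' @export
spikeRates <- function(x) {
  stopifnot(is(x, "SpikeCalls"))
  rois <- names(x@thresholds)
  n <- vapply(rois, function(r) sum(x@calls$roi == r), integer(1))
  data.frame(roi = rois, n_spikes = as.integer(n),
             rate_per_min = n / (x@duration / 60), row.names = NULL)
}

#' Baseline-normalize spike rates
#'
#' Divides each rate by the mean baseline-session rate of its culture, so a
#' normalized rate of 1 means "unchanged from baseline". By construction the
#' group mean of normalized baseline rates is 1.
#'
#' @param rates numeric vector of spike rates (per minute).
#' @param baselineMeanRate mean rate of the corresponding baseline session
#'   (> 0), recycled along `rates`.
#' @return dimensionless normalized rates.
#' @export
normalizedRate <- function(rates, baselineMeanRate) {
  if (any(baselineMeanRate <= 0)) stop("baseline mean rate must be > 0")
  rates / baselineMeanRate
}
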