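#' @include AllClasses.R
NULL

#' Run the full imaging pipeline on one seeded simulated session
#'
#' Simulate a two-channel movie, detect cells on the nuclear-channel temporal
#' mean, extract functional traces, detrend to dF/F0 and call spikes. Every
#' stage is deterministic given `seed`, so two runs with the same arguments
#' produce bit-identical outputs.
#'
#' @param seed master seed for the simulation.
#' @param spec a [MovieSpec-class].
#' @param nCells number of cells to simulate.
#' @param activity an [ActivityModel-class].
#' @param nuisance a [NuisanceModel-class].
#' @param detection a [DetectionParams-class].
#' @param traceParams a [TraceParams-class].
#' @return list with `movie`, `mask`, `traces`, `spikes`, `rates` and the
#'   ground-truth match (`match`).
#' @export
runPipeline <- function(seed = 1, spec = MovieSpec(), nCells = 30,
                        activity = ActivityModel(),
                        nuisance = NuisanceModel(),
                        detection = DetectionParams(),
                        traceParams = TraceParams()) {
  movie <- simulateCalciumMovie(spec, nCells, activity, nuisance, seed = seed)
  mask <- detectCells(temporalMean(movie, "nuclear"), detection,
                      bitDepth = movie@bitDepth)
  ts <- extractTraces(movie, mask)
  ts <- detrendNormalize(ts, traceParams)
  calls <- detectSpikes(ts, traceParams)
  list(movie = movie, mask = mask, traces = ts, spikes = calls,
       rates = spikeRates(calls),
       match = matchCells(mask, groundTruth(movie)$cells))
}

#' Score called spikes against ground truth
#'
#' Matches calls to true spike frames of the corresponding cell within
#' `tol` frames (greedy, each true spike and each call used once) and
#' reports precision, recall and F1 over all matched ROIs. Detected ROIs are
#' matched to ground-truth cells by nearest centroid (<= `centroidTol` px).
#'
#' @param result a [runPipeline()] result (needs `mask`, `spikes`, `movie`).
#' @param tol spike matching tolerance, frames.
#' @param centroidTol ROI-to-cell matching tolerance, pixels.
#' @return list with `precision`, `recall`, `f1`, `nTrue`, `nCalled`.
#' @export
scoreSpikes <- function(result, tol = 2, centroidTol = 3) {
  gt <- groundTruth(result$movie)
  tab <- roiTable(result$mask)
  calls <- spikeFrames(result$spikes)
  nMatch <- 0L
  nTrue <- sum(lengths(gt$spikes))       # every true spike counts, detected or not
  nCalled <- nrow(calls)
  for (k in seq_len(nrow(gt$cells))) {
    d <- sqrt((tab$centroid_x - gt$cells$cx[k])^2 +
              (tab$centroid_y - gt$cells$cy[k])^2)
    if (!length(d) || min(d) > centroidTol) next
    roiName <- paste0("roi", tab$label[which.min(d)])
    cf <- sort(calls$frame[calls$roi == roiName])
    usedC <- logical(length(cf))
    for (tf in gt$spikes[[k]]) {
      dist <- ifelse(usedC, Inf, abs(cf - tf))
      if (length(dist) && min(dist) <= tol) {
        jj <- which.min(dist)
        usedC[jj] <- TRUE
        nMatch <- nMatch + 1L
      }
    }
  }
  precision <- if (nCalled) nMatch / nCalled else NA_real_
  recall <- if (nTrue) nMatch / nTrue else NA_real_
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) 0
        else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       nTrue = nTrue, nCalled = nCalled)
}
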