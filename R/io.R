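#' @include AllClasses.R
NULL

.writeStack <- function(arr, path, bitDepth) {
  maxCount <- 2^bitDepth - 1
  pages <- lapply(seq_len(dim(arr)[3]), function(t) arr[, , t] / maxCount)
  tiff::writeTIFF(pages, path, bits.per.sample = if (bitDepth == 8) 8L else 16L,
                  compression = "none")
  invisible(path)
}

.readStack <- function(path, bitDepth) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (t in seq_along(pages)) arr[, , t] <- pages[[t]]
  array(as.integer(round(arr * (2^bitDepth - 1))), dim = dim(arr))
}

#' Write a movie (and its ground truth) to disk
#'
#' One multi-page TIFF per channel (`<prefix>_gcamp.tif`,
#' `<prefix>_nuclear.tif`), plus, for simulated movies, the ground truth as
#' JSON (cells and spike frames) and the label mask as a single-page TIFF
#' (`<prefix>_mask.tif`, labels scaled into the 16-bit range).
#'
#' @param movie a [CalciumMovie-class].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return invisibly, the named vector of written paths.
#' @export
writeMovie <- function(movie, dir, prefix = "movie") {
  stopifnot(is(movie, "CalciumMovie"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(gcamp = file.path(dir, paste0(prefix, "_gcamp.tif")),
             nuclear = file.path(dir, paste0(prefix, "_nuclear.tif")))
  .writeStack(movie@functional, paths["gcamp"], movie@bitDepth)
  .writeStack(movie@nuclear, paths["nuclear"], movie@bitDepth)
  gt <- movie@groundTruth
  if (length(gt)) {
    paths["truth"] <- file.path(dir, paste0(prefix, "_truth.json"))
    jsonlite::write_json(list(frame_interval_s = movie@frameInterval,
                              cells = gt$cells, spikes = gt$spikes),
                         paths["truth"], digits = NA, auto_unbox = TRUE)
    paths["mask"] <- file.path(dir, paste0(prefix, "_mask.tif"))
    tiff::writeTIFF(gt$mask / 65535, paths["mask"], bits.per.sample = 16L,
                    compression = "none")
  }
  invisible(paths)
}

#' Read a two-channel movie from TIFF stacks
#'
#' @param gcampPath,nuclearPath multi-page TIFF paths.
#' @param frameInterval seconds between frames.
#' @param bitDepth intensity bit depth the counts were written at.
#' @return a [CalciumMovie-class] (without ground truth).
#' @export
readMovie <- function(gcampPath, nuclearPath, frameInterval = 0.120,
                      bitDepth = 8) {
  new("CalciumMovie",
      functional = .readStack(gcampPath, bitDepth),
      nuclear = .readStack(nuclearPath, bitDepth),
      frameInterval = frameInterval, bitDepth = as.integer(bitDepth),
      groundTruth = list())
}

#' Write the ROI table of a label mask to CSV
#'
#' @param mask a [LabelMask-class].
#' @param path output CSV path.
#' @export
writeRoiTable <- function(mask, path) {
  utils::write.csv(roiTable(mask), path, row.names = FALSE)
  invisible(path)
}

#' Write traces / spike calls / rate summaries to CSV
#'
#' `writeTraces` writes frame, time and one dF/F (or raw) column per ROI;
#' `writeSpikes` one row per called event; `writeRateSummary` the per-ROI
#' counts and rates.
#'
#' @param ts a [TraceSet-class].
#' @param calls a [SpikeCalls-class].
#' @param path output CSV path.
#' @param assay assay to export.
#' @name trace-io
NULL

#' @rdname trace-io
#' @export
writeTraces <- function(ts, path, assay = "dff") {
  m <- SummarizedExperiment::assay(ts, assay)
  df <- data.frame(frame = SummarizedExperiment::colData(ts)$frame,
                   t_seconds = SummarizedExperiment::colData(ts)$time_s,
                   t(m), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname trace-io
#' @export
writeSpikes <- function(calls, path) {
  utils::write.csv(spikeFrames(calls), path, row.names = FALSE)
  invisible(path)
}

#' @rdname trace-io
#' @export
writeRateSummary <- function(calls, path) {
  utils::write.csv(spikeRates(calls), path, row.names = FALSE)
  invisible(path)
}
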