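#' @include AllClasses.R
NULL

#' Per-pixel temporal mean of a movie channel
#'
#' @param x an H x W x T array or a [CalciumMovie-class].
#' @param channel channel to average when `x` is a movie (nuclear by default:
#'   the static channel used for cell detection).
#' @return H x W numeric matrix.
#' @export
temporalMean <- function(x, channel = "nuclear") {
  if (is(x, "CalciumMovie")) x <- movieChannel(x, channel)
  d <- dim(x)
  if (length(d) != 3L || d[3L] < 1L) stop("need a non-empty H x W x T stack")
  rowMeans(x, dims = 2L)
}

.kernel <- function(size, shape) {
  if (shape == "square") matrix(1L, size, size)
  else {
    if (size %% 2L == 0L) stop("disc kernels need an odd size")
    EBImage::makeBrush(size, shape = "disc")
  }
}

# connected-component labeling with selectable connectivity; labels are
# assigned 1..K in raster (column-major) order of each component's first pixel
.labelComponents <- function(binary, connectivity = 8L) {
  h <- nrow(binary); w <- ncol(binary)
  lab <- matrix(0L, h, w)
  if (connectivity == 8L) {
    dr <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
    dc <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L)
    dc <- c(0L, 0L, -1L, 1L)
  }
  nextLab <- 0L
  fg <- which(binary)                      # column-major = raster order here
  for (p in fg) {
    if (lab[p] != 0L) next
    nextLab <- nextLab + 1L
    stack <- p
    lab[p] <- nextLab
    while (length(stack)) {
      q <- stack[length(stack)]; stack <- stack[-length(stack)]
      qr <- ((q - 1L) %% h) + 1L
      qc <- ((q - 1L) %/% h) + 1L
      nr <- qr + dr; nc <- qc + dc
      ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
      nb <- (nc[ok] - 1L) * h + nr[ok]
      nb <- nb[binary[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- nextLab
        stack <- c(stack, nb)
      }
    }
  }
  lab
}

.maskTable <- function(mask) {
  labs <- sort(unique(mask[mask > 0]))
  if (!length(labs))
    return(data.frame(label = integer(), area = integer(),
                      centroid_x = numeric(), centroid_y = numeric()))
  h <- nrow(mask)
  px <- which(mask > 0)
  lb <- mask[px]
  rows <- ((px - 1L) %% h) + 1L
  cols <- ((px - 1L) %/% h) + 1L
  data.frame(label = labs,
             area = as.integer(tabulate(lb, max(labs))[labs]),
             centroid_x = as.numeric(tapply(cols, lb, mean)[as.character(labs)]),
             centroid_y = as.numeric(tapply(rows, lb, mean)[as.character(labs)]))
}

#' Detect cells in a time-averaged nuclear image
#'
#' The detection chain, in order: median blur; grayscale morphological
#' opening with the large background kernel to estimate background, which is
#' subtracted (clipped at zero); a second small opening to sharpen cell
#' contours; binary thresholding; connected-component labeling; rejection of
#' components with area `<= minArea` (strict inequality keeps 21 px, drops
#' 20 px at the default); relabeling 1..K in raster order.
#'
#' @param image H x W matrix of counts within the bit depth, typically
#'   [temporalMean()] of the nuclear channel.
#' @param params a [DetectionParams-class].
#' @param bitDepth intensity bit depth of `image`.
#' @return a [LabelMask-class].
#' @export
detectCells <- function(image, params = DetectionParams(), bitDepth = 8) {
  stopifnot(is.matrix(image), is(params, "DetectionParams"))
  validObject(params)
  if (params@backgroundKernel > min(dim(image)) ||
      params@sharpenKernel > min(dim(image)))
    stop("kernel larger than image")
  maxCount <- 2^bitDepth - 1
  img <- pmin(pmax(image / maxCount, 0), 1)

  blurred <- if (params@medianBlurSize > 1L)
    EBImage::medianFilter(img, (params@medianBlurSize - 1L) %/% 2L)
  else img
  background <- EBImage::opening(blurred,
                                 .kernel(params@backgroundKernel, params@kernelShape))
  fg <- pmax(blurred - background, 0)
  sharp <- EBImage::opening(fg, .kernel(params@sharpenKernel, params@kernelShape))
  binary <- (sharp * maxCount) > params@threshold

  lab <- .labelComponents(binary, params@connectivity)
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L], max(lab))
    keep <- which(areas > params@minArea)
    relab <- integer(max(lab))
    relab[keep] <- seq_along(keep)
    lab[lab > 0L] <- relab[lab[lab > 0L]]
  }
  new("LabelMask", mask = lab, table = .maskTable(lab))
}

#' Mean ROI intensity of a maximum projection
#'
#' Per-pixel maximum over the planes of a z-stack, then the mean over an ROI
#' pixel set (or the whole frame).
#'
#' @param zstack H x W x Z array (Z >= 1).
#' @param mask optional [LabelMask-class] or integer matrix selecting the ROI.
#' @param label ROI label within `mask`; ignored when `mask` is NULL
#'   (whole-frame quantification).
#' @return mean intensity, counts.
#' @export
maxProjectRoiMean <- function(zstack, mask = NULL, label = 1L) {
  d <- dim(zstack)
  if (length(d) != 3L || d[3L] < 1L) stop("need a non-empty H x W x Z stack")
  mp <- zstack[, , 1L]
  if (d[3L] > 1L) for (k in 2:d[3L]) mp <- pmax(mp, zstack[, , k])
  if (is.null(mask)) return(mean(mp))
  if (is(mask, "LabelMask")) mask <- labelMatrix(mask)
  px <- mask == label
  if (!any(px)) stop("empty ROI: no pixels with label ", label)
  mean(mp[px])
}

#' Match detected cells against ground truth by centroid distance
#'
#' Greedy nearest-centroid matching within `tol` pixels; each truth cell and
#' each detection is used at most once. Recall and precision can be
#' restricted to truth cells above a minimum area.
#'
#' @param detected a [LabelMask-class].
#' @param truthCells ground-truth cell table (columns `cx`, `cy`, `radius`).
#' @param tol centroid matching tolerance, pixels.
#' @param minTruthArea only truth cells whose disk area is at least this many
#'   pixels count toward recall (small cells may legitimately fail the area
#'   filter).
#' @return list with `recall`, `precision`, `nMatched`, `nTruth`, `nDetected`.
#' @export
matchCells <- function(detected, truthCells, tol = 3, minTruthArea = 0) {
  tab <- roiTable(detected)
  truthArea <- pi * truthCells$radius^2
  truth <- truthCells[truthArea >= minTruthArea, , drop = FALSE]
  nT <- nrow(truth); nD <- nrow(tab)
  usedD <- logical(nD)
  nMatch <- 0L
  if (nT && nD) {
    dmat <- outer(truth$cx, tab$centroid_x, `-`)^2 +
            outer(truth$cy, tab$centroid_y, `-`)^2
    dmat <- sqrt(dmat)
    for (it in seq_len(nT)) {
      j <- which.min(ifelse(usedD, Inf, dmat[it, ]))
      if (length(j) && dmat[it, j] <= tol && !usedD[j]) {
        usedD[j] <- TRUE
        nMatch <- nMatch + 1L
      }
    }
  }
  list(recall = if (nT) nMatch / nT else NA_real_,
       precision = if (nD) nMatch / nD else NA_real_,
       nMatched = nMatch, nTruth = nT, nDetected = nD)
}
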