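test_that("temporal mean is the per-pixel average over frames", {
  a <- array(7, dim = c(4, 5, 3))
  expect_equal(temporalMean(a), matrix(7, 4, 5))
  two <- array(c(rep(0, 12), rep(200, 12)), dim = c(3, 4, 2))
  expect_equal(temporalMean(two), matrix(100, 3, 4))

  set.seed(1)
  r <- array(runif(4 * 3 * 6, 0, 255), dim = c(4, 3, 6))
  oracle <- matrix(0, 4, 3)
  for (i in 1:4) for (j in 1:3) oracle[i, j] <- mean(r[i, j, ])
  expect_equal(temporalMean(r), oracle)
  expect_error(temporalMean(array(0, c(4, 4, 0))), "non-empty")
})

test_that("component labeling agrees with EBImage and honors connectivity", {
  set.seed(5)
  b <- matrix(runif(64 * 64) < 0.3, 64, 64)
  ours4 <- stimchip:::.labelComponents(b, 4L)
  ref <- EBImage::bwlabel(b)                  # EBImage labels 4-connected
  # identical partitions (label ids may differ): compare co-membership
  expect_equal(max(ours4), max(ref))
  key <- paste(ours4[b], ref[b])
  expect_equal(length(unique(key)), max(ref))

  diagPair <- matrix(FALSE, 4, 4); diagPair[1, 1] <- diagPair[2, 2] <- TRUE
  expect_equal(max(stimchip:::.labelComponents(diagPair, 4L)), 2)
  expect_equal(max(stimchip:::.labelComponents(diagPair, 8L)), 1)
})

test_that("the detection chain finds planted disks and nothing else", {
  expect_equal(nCells(detectCells(matrix(0, 128, 128))), 0)

  # 10 disks (r = 3 -> ~29 px) at intensity 180 over flat background 20
  set.seed(8)
  img <- matrix(20, 128, 128)
  centers <- expand.grid(x = c(20, 45, 70, 95, 120), y = c(30, 90))
  for (k in 1:10)
    for (r in 1:128) for (cc in 1:128)
      if ((r - centers$y[k])^2 + (cc - centers$x[k])^2 <= 9)
        img[r, cc] <- 180
  res <- detectCells(img)
  expect_equal(nCells(res), 10)
  tab <- roiTable(res)
  ord <- order(tab$centroid_y, tab$centroid_x)
  expect_equal(tab$centroid_x[ord], rep(c(20, 45, 70, 95, 120), 2),
               tolerance = 0.05)

  # staged cross-check: on structure << kernel the background opening leaves
  # a brute-force-identical foreground (odd kernel, shared edge convention)
  p <- DetectionParams(medianBlurSize = 1, backgroundKernel = 31,
                       sharpenKernel = 1)
  small <- img[1:60, 1:60]
  bg <- bruteOpening(small / 255, 31)
  fgOracle <- pmax(small / 255 - bg, 0) * 255
  binOracle <- fgOracle > 100
  resSmall <- detectCells(small, p)
  lab <- labelMatrix(resSmall)
  expect_identical(lab > 0, binOracle & TRUE)
})

test_that("the area filter is strictly greater-than", {
  # rectangles of exactly 20 px and 21 px; neutral kernels isolate the filter
  img <- matrix(0, 64, 64)
  img[10:13, 10:14] <- 180                    # 4 x 5 = 20 px -> rejected
  img[40:43, 40:44] <- 180; img[44, 40] <- 180  # 21 px -> kept
  p <- DetectionParams(medianBlurSize = 1, backgroundKernel = 63,
                       sharpenKernel = 1)
  res <- detectCells(img, p)
  expect_equal(nCells(res), 1)
  expect_equal(roiTable(res)$area, 21L)
  expect_gte(roiTable(res)$centroid_x, 40)
})

test_that("raising the threshold never increases the cell count", {
  set.seed(12)
  mv <- simulateCalciumMovie(tinySpec(nFrames = 40, seed = 12), nCells = 12,
                             seed = 12)
  avg <- temporalMean(mv)
  counts <- vapply(seq(40, 220, by = 20), function(th)
    nCells(detectCells(avg, DetectionParams(threshold = th))), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("a constant offset removed by the background opening is invisible", {
  set.seed(13)
  mv <- simulateCalciumMovie(tinySpec(nFrames = 40, seed = 13), nCells = 10,
                             seed = 13, nuisance = NuisanceModel(noiseSigma = 0))
  avg <- temporalMean(mv)
  base <- detectCells(avg)
  shifted <- detectCells(avg + 25)
  expect_identical(labelMatrix(base), labelMatrix(shifted))
})

test_that("max projection ROI means match a brute-force oracle", {
  set.seed(3)
  z <- array(runif(6 * 6 * 4, 0, 255), dim = c(6, 6, 4))
  roi <- matrix(0L, 6, 6); roi[2:4, 2:3] <- 1L
  # loop oracle
  mp <- matrix(-Inf, 6, 6)
  for (i in 1:6) for (j in 1:6) mp[i, j] <- max(z[i, j, ])
  expect_equal(maxProjectRoiMean(z, roi), mean(mp[roi == 1L]))
  expect_equal(maxProjectRoiMean(z), mean(mp))

  one <- z[, , 1, drop = FALSE]
  expect_equal(maxProjectRoiMean(one, roi), mean(z[, , 1][roi == 1L]))
  withZero <- array(c(z[, , 2], matrix(0, 6, 6)), dim = c(6, 6, 2))
  expect_equal(maxProjectRoiMean(withZero, roi), mean(z[, , 2][roi == 1L]))
  expect_error(maxProjectRoiMean(z, roi, label = 9L), "empty ROI")
})
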