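test_that("rolling median equals the brute-force sliding-window oracle", {
  set.seed(21)
  for (w in c(2, 5, 20, 21)) {
    x <- cumsum(rnorm(300)) + rnorm(300, 0, 3)
    expect_identical(rollingMedian(x, w), bruteRollMedian(x, w))
  }
  expect_error(rollingMedian(1:10, 1), "window")
})

test_that("trace extraction is the spatial mean over each ROI", {
  # uniform frames give constant traces
  a <- array(rep(c(10, 20, 30), each = 16), dim = c(4, 4, 3))
  mask <- matrix(0L, 4, 4); mask[2:3, 2:3] <- 1L
  ts <- extractTraces(a, mask, frameInterval = 0.12)
  expect_equal(unname(SummarizedExperiment::assay(ts, "raw")[1, ]),
               c(10, 20, 30))

  # single-pixel ROI equals that pixel's series
  m1 <- matrix(0L, 4, 4); m1[3, 2] <- 1L
  set.seed(2)
  r <- array(runif(4 * 4 * 10, 0, 255), dim = c(4, 4, 10))
  ts1 <- extractTraces(r, m1, frameInterval = 0.12)
  expect_equal(unname(SummarizedExperiment::assay(ts1, "raw")[1, ]), r[3, 2, ])

  # random movie vs per-frame loop oracle, two ROIs
  m2 <- matrix(0L, 4, 4); m2[1:2, 1] <- 1L; m2[4, 3:4] <- 2L
  ts2 <- extractTraces(r, m2, frameInterval = 0.12)
  oracle <- sapply(1:10, function(t) c(mean(r[, , t][m2 == 1L]),
                                       mean(r[, , t][m2 == 2L])))
  expect_equal(unname(SummarizedExperiment::assay(ts2, "raw")), unname(oracle))
  expect_error(extractTraces(r, matrix(0L, 4, 4), frameInterval = 0.12),
               "no labeled")
})

test_that("detrending gives a flat dF/F0 on constant and ramp traces", {
  mkTs <- function(v) {
    arr <- array(rep(v, each = 1), dim = c(1, 1, length(v)))
    extractTraces(arr, matrix(1L, 1, 1), frameInterval = 0.12)
  }
  ts <- detrendNormalize(mkTs(rep(80, 100)))
  expect_equal(unname(SummarizedExperiment::assay(ts, "trend")[1, ]),
               rep(80, 100))
  expect_equal(unname(SummarizedExperiment::assay(ts, "dff")[1, ]),
               rep(0, 100))

  # linear ramp: the rolling median tracks the ramp away from the edges
  ramp <- seq(100, 150, length.out = 200)
  tsR <- detrendNormalize(mkTs(ramp))
  dff <- SummarizedExperiment::assay(tsR, "dff")[1, ]
  inner <- 21:180
  # an even centered window sits half a sample off the ramp at the centre
  slope <- diff(ramp)[1]
  expect_lt(max(abs(dff[inner])), 0.51 * slope / mean(ramp))
  # edge deviation bounded by half a window of ramp slope over the trend mean
  expect_lt(max(abs(dff)), 10 * slope / mean(ramp) + 1e-12)

  expect_error(detrendNormalize(mkTs(rep(10, 15))), "shorter")
})

test_that("dF/F0 is invariant to rescaling the raw fluorescence", {
  set.seed(9)
  v <- 100 + cumsum(rnorm(150, 0, 0.5)) + 20 * (runif(150) < 0.05)
  arr <- function(x) array(x, dim = c(1, 1, length(x)))
  ts1 <- detrendNormalize(extractTraces(arr(v), matrix(1L, 1, 1), 0.12))
  ts2 <- detrendNormalize(extractTraces(arr(3.7 * v), matrix(1L, 1, 1), 0.12))
  expect_equal(SummarizedExperiment::assay(ts1, "dff"),
               SummarizedExperiment::assay(ts2, "dff"))
})

test_that("spike calling thresholds at mean + k SD and merges runs", {
  # constant trace: no calls
  cs <- detectSpikes(traceSetWithDff(rep(0.02, 400)))
  expect_equal(nrow(spikeFrames(cs)), 0)

  # 5 isolated rectangular transients, 10x the baseline SD
  set.seed(31)
  base <- rnorm(1000, 0, 0.01)
  dff <- base
  at <- c(100, 300, 500, 700, 900)
  for (f in at) dff[f:(f + 2)] <- dff[f:(f + 2)] + 10 * 0.01
  ts <- traceSetWithDff(dff)
  cs <- detectSpikes(ts)
  called <- spikeFrames(cs)$frame
  expect_equal(length(called), 5)
  expect_true(all(abs(outer(called, at, `-`)) |> apply(1, min) <= 2))
  # brute-force upward-crossing count at the same threshold
  theta <- mean(dff) + 3 * sd(dff)
  crossings <- sum(diff(dff > theta) == 1)
  expect_equal(length(called), crossings)

  # two supra-threshold runs separated by one sub-threshold frame merge
  d2 <- rep(0, 200); d2[50:52] <- 1; d2[54:56] <- 0.9
  d2 <- d2 + rnorm(200, 0, 0.001)
  cs2 <- detectSpikes(traceSetWithDff(d2), TraceParams(minSeparation = 2))
  expect_equal(nrow(spikeFrames(cs2)), 1)
  cs3 <- detectSpikes(traceSetWithDff(d2), TraceParams(minSeparation = 0))
  expect_equal(nrow(spikeFrames(cs3)), 2)
})

test_that("spike count is non-increasing in the SD multiplier k", {
  set.seed(41)
  mv <- simulateCalciumMovie(tinySpec(nFrames = 250, seed = 41), nCells = 8,
                             seed = 41)
  mask <- detectCells(temporalMean(mv))
  ts <- detrendNormalize(extractTraces(mv, mask))
  counts <- vapply(c(1, 2, 3, 4, 6), function(k)
    nrow(spikeFrames(detectSpikes(ts, TraceParams(spikeK = k)))), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("rates normalize against the baseline mean", {
  expect_equal(normalizedRate(c(2, 2, 2), 2), c(1, 1, 1))
  expect_equal(normalizedRate(3, 2), 1.5)
  set.seed(6)
  rates <- rexp(40, 1 / 2)
  norm <- normalizedRate(rates, mean(rates))
  expect_equal(mean(norm), 1)                 # group mean is 1 by construction
  expect_error(normalizedRate(1, 0), "> 0")
})
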