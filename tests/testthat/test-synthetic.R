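test_that("cell placement is disjoint, in-frame and deterministic", {
  spec <- tinySpec()
  expect_equal(nrow(sampleCells(spec, 0)), 0)
  c1 <- sampleCells(spec, 15, seed = 5)
  c2 <- sampleCells(spec, 15, seed = 5)
  expect_identical(c1, c2)

  big <- sampleCells(MovieSpec(seed = 9), 30)
  # all-pairs brute-force disjointness and containment
  for (a in 1:29) for (b in (a + 1):30) {
    d <- sqrt((big$cx[a] - big$cx[b])^2 + (big$cy[a] - big$cy[b])^2)
    expect_gt(d, big$radius[a] + big$radius[b])
  }
  expect_true(all(big$cx - big$radius >= 1 & big$cx + big$radius <= 128))
  expect_true(all(big$cy - big$radius >= 1 & big$cy + big$radius <= 128))

  expect_error(sampleCells(tinySpec(), 500, maxTries = 600), "non-overlapping")
})

test_that("spike trains mix shared network events and private events", {
  spec <- tinySpec()
  cells <- sampleCells(spec, 8, seed = 2)

  quiet <- simulateSpikes(cells, ActivityModel(0, 0, 0), spec, seed = 1)
  expect_true(all(lengths(quiet) == 0))

  sync <- simulateSpikes(cells, ActivityModel(networkEventRate = 10,
                                              networkParticipation = 1,
                                              privateRate = 0), spec, seed = 1)
  for (k in 2:8) expect_identical(sync[[k]], sync[[1]])
})

test_that("long-run spike rates match the Poisson expectation", {
  # 200 simulated minutes; rendering skipped, only trains are drawn
  spec <- MovieSpec(height = 64, width = 64, nFrames = 100000,
                    frameInterval = 0.12, seed = 3)
  durMin <- spec@nFrames * spec@frameInterval / 60
  act <- ActivityModel(networkEventRate = 4, networkParticipation = 0.7,
                       privateRate = 1.5)
  cells <- sampleCells(spec, 4, seed = 3)
  trains <- simulateSpikes(cells, act, spec, seed = 11)
  lambda <- act@networkEventRate * act@networkParticipation + act@privateRate
  for (k in seq_along(trains)) {
    rate <- length(trains[[k]]) / durMin
    se <- sqrt(lambda / durMin)              # Poisson SE of the rate estimate
    expect_lt(abs(rate - lambda), 3 * se)
  }
})

test_that("rendering follows the transient kernel and is pixel-exact", {
  spec <- tinySpec(nFrames = 60)
  cells <- sampleCells(spec, 5, seed = 4)
  still <- NuisanceModel(bleachTau = Inf, noiseSigma = 0)

  # no spikes, no noise, unit trend: constant in time everywhere
  mv <- renderMovie(cells, rep(list(integer(0)), 5), ActivityModel(), still,
                    spec, seed = 1)
  fun <- movieChannel(mv, "functional")
  expect_true(all(apply(fun, c(1, 2), function(v) length(unique(v))) == 1))

  # ground-truth mask equals independently rasterized disks, pixel-exact
  gt <- groundTruth(mv)
  ref <- matrix(0L, 64, 64)
  for (k in 1:5)
    for (r in 1:64) for (cc in 1:64)
      if ((r - cells$cy[k])^2 + (cc - cells$cx[k])^2 <= cells$radius[k]^2)
        ref[r, cc] <- k
  expect_identical(gt$mask, ref)

  # nuclear channel is the exact disk indicator each frame at zero noise
  nuc <- movieChannel(mv, "nuclear")
  for (t in c(1, 30, 60)) {
    fr <- nuc[, , t]
    expect_true(all(fr[ref == 0] == 20))
    for (k in 1:5)
      expect_true(all(fr[ref == k] == as.integer(round(cells$nuclear_intensity[k]))))
  }

  # a single spike at frame k peaks there and decays with tau
  act <- ActivityModel(transientAmplitude = 0.4, decayTau = 0.4)
  kSpike <- 20L
  mv2 <- renderMovie(cells, c(list(kSpike), rep(list(integer(0)), 4)),
                     act, still, spec, seed = 1)
  px <- groundTruth(mv2)$mask == 1L
  trace <- vapply(seq_len(60), function(t) mean(movieChannel(mv2)[, , t][px]),
                  numeric(1))
  expect_equal(which.max(trace), kSpike)
  f0 <- cells$f0[1]                    # true (unquantized) baseline
  tSec <- (seq_len(60) - kSpike) * spec@frameInterval
  kernel <- ifelse(tSec >= 0, 1 + 0.4 * exp(-tSec / 0.4), 1)
  # all pixels of a cell share one value, so rounding to 8-bit counts bounds
  # the in-cell mean deviation by half a count
  expect_lt(max(abs(trace - f0 * kernel)), 0.51)
  # peak dF/F matches the transient amplitude up to quantization
  expect_equal((max(trace) - f0) / f0, 0.4, tolerance = 0.02)
})

test_that("simulation is fully deterministic under a master seed", {
  spec <- tinySpec(nFrames = 80)
  m1 <- simulateCalciumMovie(spec, nCells = 10, seed = 21)
  m2 <- simulateCalciumMovie(spec, nCells = 10, seed = 21)
  expect_identical(movieChannel(m1), movieChannel(m2))
  expect_identical(movieChannel(m1, "nuclear"), movieChannel(m2, "nuclear"))
  expect_identical(groundTruth(m1), groundTruth(m2))
})
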