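test_that("trivial topologies split current as expected", {
  # single series branch carries everything
  net <- ResistorNetwork(data.frame(from = "a", to = "b", resistance = 100),
                         list(from = "a", to = "b", current = 2e-3))
  expect_equal(solveNetwork(net)$current, 2e-3)

  # two equal parallel resistors split 50/50
  net <- ResistorNetwork(data.frame(from = c("a", "a"), to = c("b", "b"),
                                    resistance = c(100, 100)),
                         list(from = "a", to = "b", current = 1e-3))
  expect_equal(solveNetwork(net)$current, c(0.5e-3, 0.5e-3))
})

test_that("parallel branches follow the closed-form current divider", {
  # 2R vs 2.2R: 2.2/(2+2.2) through the smaller branch
  for (R in c(1, 37.5, 1080)) {
    net <- ResistorNetwork(
      data.frame(from = c("a", "a"), to = c("b", "b"),
                 resistance = c(2 * R, 2.2 * R)),
      list(from = "a", to = "b", current = 43.5e-6))
    sol <- solveNetwork(net)
    expect_equal(sol$current[1] / 43.5e-6, 2.2 / 4.2, tolerance = 1e-12)
    expect_equal(sol$current[2] / 43.5e-6, 2 / 4.2, tolerance = 1e-12)
  }

  # random two-branch dividers vs i1 = i * R2/(R1+R2)
  set.seed(42)
  for (rep in 1:25) {
    R12 <- runif(2, 1, 1e4); i <- runif(1, 1e-6, 1e-2)
    net <- ResistorNetwork(
      data.frame(from = c("a", "a"), to = c("b", "b"), resistance = R12),
      list(from = "a", to = "b", current = i))
    sol <- solveNetwork(net)
    expect_equal(sol$current[1], i * R12[2] / sum(R12), tolerance = 1e-12)
  }
})

test_that("Kirchhoff's current law holds on random networks", {
  set.seed(7)
  for (rep in 1:30) {
    net <- randomNetwork(nNodes = sample(4:12, 1), nExtra = sample(2:10, 1),
                         current = 10^runif(1, -6, -2))
    sol <- solveNetwork(net)
    res <- nodeResiduals(sol, net@source)
    expect_lt(max(abs(res)), 1e-9 * net@source$current)
  }
})

test_that("section fields scale linearly with the drive current", {
  g <- ChannelGeometry(10e-3, 7.7e-3, 0.8e-3, "s1")
  ed <- data.frame(from = c("a", "a"), to = c("b", "b"),
                   resistance = c(NA, 500), label = c("s1", "byp"))
  mk <- function(i) ResistorNetwork(ed, list(from = "a", to = "b", current = i),
                                    geometries = list(s1 = g), medium = mediumPBS)
  f1 <- sectionFields(mk(43.5e-6), mediumPBS)
  f3 <- sectionFields(mk(3 * 43.5e-6), mediumPBS)
  expect_equal(f3, 3 * f1)
  f0 <- sectionFields(mk(0), mediumPBS)        # zero drive, zero field
  expect_equal(unname(f0["s1"]), 0)
  expect_error(sectionFields(mk(1e-3), mediumPBS, sections = "s9"), "unknown")
})

test_that("the example chamber config yields ordered fields s1 > s2 > s3", {
  cfg <- readChamberConfig(system.file("extdata", "example_chamber.yaml",
                                       package = "stimchip"))
  f <- sectionFields(cfg$network, cfg$electrolyte)[c("s1", "s2", "s3")]
  expect_true(f["s1"] > f["s2"] && f["s2"] > f["s3"])
  # the config is engineered to the 4.7 / 2.7 / 1.0 mV/mm design point
  expect_equal(unname(f), c(4.7, 2.7, 1.0), tolerance = 1e-9)
  # KCL on the solved config
  res <- nodeResiduals(solveNetwork(cfg$network), cfg$network@source)
  expect_lt(max(abs(res)), 1e-9 * cfg$network@source$current)
})

test_that("invalid networks are rejected", {
  expect_error(ResistorNetwork(
    data.frame(from = c("a", "c"), to = c("b", "d"), resistance = c(1, 1)),
    list(from = "a", to = "d", current = 1)), "not connected")
  expect_error(ResistorNetwork(
    data.frame(from = "a", to = "b", resistance = -1),
    list(from = "a", to = "b", current = 1)), "positive")
  expect_error(ResistorNetwork(
    data.frame(from = "a", to = "b", resistance = 1),
    list(from = "a", to = "z", current = 1)), "nodes")
})
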