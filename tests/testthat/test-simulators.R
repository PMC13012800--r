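test_that("vanishing variance collapses all nodes onto the root", {
  topo <- fixtureTrees()[[1]]
  cfg <- simulationConfig(seed = 1, sigma2 = 1e-12,
                          rootLocation = c(2, 1))
  nd <- nodeData(simulateRRWOnTree(topo, cfg)$tree)
  d <- greatCircleDistance(c(2, 1), cbind(nd$lon, nd$lat))
  expect_lt(max(d), 1e-4)
})

test_that("BRW displacements have the Gaussian moments and law", {
  # two-branch cherry with durations 1 and 2, many replicate seeds
  nodes <- data.frame(id = 1:3, parent = c(NA, 1L, 1L), time = c(0, 1, 2),
                      lon = 0, lat = 0, label = c(NA, "A", "B"),
                      stringsAsFactors = FALSE)
  cherry <- new("GeoTree", nodes = nodes, annotations = list(),
                mostRecentDate = 2, projected = TRUE, treeIndex = 1L)
  sigma2 <- 3
  disp <- vapply(1:1500, function(s) {
    nd <- nodeData(simulateRRWOnTree(
      cherry, simulationConfig(seed = s, sigma2 = sigma2))$tree)
    c(nd$lon[2], nd$lat[2], nd$lon[3], nd$lat[3])
  }, numeric(4))
  # per-axis variance sigma2 * t within 5%
  expect_equal(mean(disp[1, ]^2 + disp[2, ]^2) / 2, sigma2 * 1,
               tolerance = 0.05)
  expect_equal(mean(disp[3, ]^2 + disp[4, ]^2) / 2, sigma2 * 2,
               tolerance = 0.05)
  # standardised per-axis displacements pass a KS test against N(0,1)
  z <- c(disp[1, ] / sqrt(sigma2), disp[2, ] / sqrt(sigma2),
         disp[3, ] / sqrt(2 * sigma2), disp[4, ] / sqrt(2 * sigma2))
  expect_gt(stats::ks.test(z, "pnorm")$p.value, 0.01)
})

test_that("per-branch seeding makes runs reproducible and nested", {
  topo <- fixtureTrees()[[2]]
  cfg <- simulationConfig(seed = 77, sigma2 = 100)
  a <- simulateRRWOnTree(topo, cfg)$table
  b <- simulateRRWOnTree(topo, cfg)$table
  expect_identical(branchData(a), branchData(b))
  # kSim = 0 env-modulated run is bit-identical to the plain run
  u <- uniformRaster()
  c0 <- simulateEnvDependentRRW(topo, u,
                                simulationConfig(seed = 77, sigma2 = 100,
                                                 kSim = 0))$table
  expect_identical(branchData(c0), branchData(a))
})

test_that("birth-death simulator honours the stop rules and Yule depths", {
  cfg <- simulationConfig(seed = 3, lambda = 1, mu = 0, stopTipCount = 50)
  out <- simulateBirthDeathDiffusion(cfg)
  expect_equal(nTips(out$tree), 50L)
  expect_equal(nrow(branchData(out$table)), 98L)  # 2n - 2
  expect_error(simulateBirthDeathDiffusion(
    simulationConfig(seed = 1, lambda = 1, mu = 2, stopTipCount = 10)),
    "lambda > mu")
  expect_error(simulateBirthDeathDiffusion(
    simulationConfig(seed = 1, lambda = 1, mu = 0)), "exactly one")
  # Yule: E[total depth to reach N tips] = sum_{k<N} 1/(k lambda)
  dep <- vapply(1:250, function(s) {
    tr <- simulateBirthDeathDiffusion(
      simulationConfig(seed = 100 + s, lambda = 1, mu = 0,
                       stopTipCount = 30))$tree
    nd <- nodeData(tr)
    max(nd$time)  # the process starts at time 0
  }, 0)
  expect_equal(mean(dep), sum(1 / (1:29)), tolerance = 0.10)
  # time-stop rule caps the tree height
  tt <- simulateBirthDeathDiffusion(
    simulationConfig(seed = 5, lambda = 1.2, mu = 0.2, stopTime = 4))
  expect_lte(max(nodeData(tt$tree)$time), 4 + 1e-12)
})

test_that("extinct lineages are pruned unless kept", {
  cfg <- simulationConfig(seed = 11, lambda = 1, mu = 0.4, stopTipCount = 40)
  pruned <- simulateBirthDeathDiffusion(cfg)
  expect_equal(nTips(pruned$tree), 40L)
  expect_false(any(grepl("^x", tipLabels(pruned$tree))))
  kept <- simulateBirthDeathDiffusion(cfg, keepExtinct = TRUE)
  expect_gt(nTips(kept$tree), 40L)
  expect_true(any(grepl("^x", tipLabels(kept$tree))))
})

test_that("heavier RRW tails raise the diffusion-coefficient heterogeneity", {
  topo <- fixtureTrees()[[1]]
  cvAt <- function(nu) {
    mean(vapply(1:40, function(s) {
      tb <- simulateRRWOnTree(topo, simulationConfig(
        seed = 1000 * nu + s, mode = "RRW", sigma2 = 100, nu = nu))$table
      D <- branchDiffusionCoefficients(tb)
      stats::sd(D) / mean(D)
    }, 0))
  }
  cvs <- vapply(c(0.5, 1, 5, 50), cvAt, 0)
  expect_true(all(diff(cvs) < 0))  # CV decreases towards the BRW limit
})

test_that("a masked barrier is never crossed by simulated endpoints", {
  half <- halfRaster()
  m <- rasterValues(half)
  m[m == 0] <- NA  # mask the west half entirely
  barrier <- envRaster(m, half@xll, half@yll, half@cellSize, "mask")
  topo <- fixtureTrees()[[1]]
  sim <- simulateRRWOnTree(topo, simulationConfig(seed = 2, sigma2 = 3000,
                                                  rootLocation = c(2.5, 0)),
                           raster = barrier)
  nd <- nodeData(sim$tree)
  expect_false(anyNA(rasterValueAt(barrier, cbind(nd$lon, nd$lat))))
  # an over-dispersed walk in a tiny corridor exhausts the rejection cap
  tiny <- envRaster(matrix(1, 2, 2), 0, 0, 0.001, "tiny")
  expect_error(simulateRRWOnTree(
    topo, simulationConfig(seed = 2, sigma2 = 5e4, rootLocation = c(0.001, 0.001),
                           rejectionCap = 50L), raster = tiny),
    "rejection cap")
})

test_that("environmental modulation scales variance by the local multiplier", {
  topo <- fixtureTrees()[[2]]
  u <- uniformRaster()  # constant value: multiplier = 1/(1 + kSim)
  kSim <- 4
  base <- simulateRRWOnTree(topo, simulationConfig(seed = 9, sigma2 = 200))
  mod <- simulateEnvDependentRRW(topo, u, simulationConfig(
    seed = 9, sigma2 = 200, kSim = kSim, rasterType = "resistance"))
  wdcRatio <- weightedDiffusionCoefficient(mod$table) /
    weightedDiffusionCoefficient(base$table)
  expect_equal(wdcRatio, 1 / (1 + kSim), tolerance = 0.10)
})

test_that("lineages slow down in high-resistance regions", {
  half <- halfRaster()  # 0 in the west, 1 in the east
  reps <- lapply(1:60, function(s) {
    topo <- simulateBirthDeathDiffusion(simulationConfig(
      seed = 3000 + s, lambda = 1, mu = 0, stopTipCount = 20))$tree
    tb <- simulateEnvDependentRRW(topo, half, simulationConfig(
      seed = 3000 + s, sigma2 = 2000, kSim = 20,
      rasterType = "resistance"))$table
    br <- branchData(tb)
    side <- rasterValueAt(half, cbind(br$startLon, br$startLat))
    c(lo = mean(br$greatCircleDistance_km[side == 0]),
      hi = mean(br$greatCircleDistance_km[side == 1]))
  })
  lo <- mean(vapply(reps, `[[`, 0, "lo"), na.rm = TRUE)
  hi <- mean(vapply(reps, `[[`, 0, "hi"), na.rm = TRUE)
  expect_lt(hi, lo)
})

test_that("direction-only resampling conserves observed branch lengths", {
  tr <- fixtureTrees()[[1]]
  out <- simulateRRWOnTree(tr, simulationConfig(seed = 4, sigma2 = 1,
                                                conserveDistances = TRUE,
                                                rootLocation = c(0, 0)))
  obs <- sort(branchData(extractBranchTable(tr))$greatCircleDistance_km)
  got <- sort(branchData(out$table)$greatCircleDistance_km)
  expect_equal(got, obs, tolerance = 1e-6)
})

test_that("simulated tables satisfy the extraction-table contract", {
  out <- simulateBirthDeathDiffusion(simulationConfig(
    seed = 21, mode = "RRW", nu = 1, sigma2 = 150, lambda = 1, mu = 0.2,
    stopTipCount = 25))
  expect_true(validObject(out$table))
  expect_true(validObject(out$tree))
  expect_equal(nrow(branchData(out$table)), 2L * nTips(out$tree) - 2L)
  # downstream operations accept the simulated output
  expect_gt(weightedDiffusionCoefficient(out$table), 0)
  expect_no_error(wavefrontSeries(out$table,
                                  seq(min(branchData(out$table)$startTime),
                                      max(branchData(out$table)$endTime),
                                      length.out = 5)))
  expect_no_error(ibdSignal(out$table, out$tree))
})
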