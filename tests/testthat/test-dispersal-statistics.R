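test_that("weighted dispersal velocity is the distance/time ratio", {
  expect_equal(weightedDispersalVelocity(makeTable(d = 2, t = 1)), 2)
  expect_equal(weightedDispersalVelocity(makeTable(d = c(2, 4), t = c(1, 3))),
               1.5)
  tb <- fixtureTables()[[1]]
  br <- branchData(tb)
  brute <- sum(br$greatCircleDistance_km) / sum(br$duration)  # summation oracle
  expect_equal(weightedDispersalVelocity(tb), brute, tolerance = 1e-12)
  empty <- phylospread:::.newExtractionTable(br[0, ])
  expect_error(weightedDispersalVelocity(empty), "empty")
})

test_that("weighted diffusion coefficient follows d^2/(4t) weighting", {
  expect_equal(weightedDiffusionCoefficient(makeTable(d = 2, t = 1)), 1)
  expect_equal(weightedDiffusionCoefficient(makeTable(d = c(2, 4),
                                                      t = c(1, 1))), 2.5)
  tb <- fixtureTables()[[2]]
  br <- branchData(tb)
  expect_equal(weightedDiffusionCoefficient(tb),
               sum(br$greatCircleDistance_km^2) / (4 * sum(br$duration)))
  expect_equal(branchDiffusionCoefficients(tb),
               br$greatCircleDistance_km^2 / (4 * br$duration))
  # invariant under row reordering
  shuf <- phylospread:::.newExtractionTable(br[sample(nrow(br)), ])
  expect_equal(weightedDiffusionCoefficient(shuf),
               weightedDiffusionCoefficient(tb))
})

test_that("doubling durations halves velocity and diffusion coefficient", {
  tb <- fixtureTables()[[3]]
  br <- branchData(tb)
  br$duration <- br$duration * 2
  br$endTime <- br$startTime + br$duration
  # keep node2 times consistent enough for the constructor
  doubled <- phylospread:::.newExtractionTable(br)
  expect_equal(weightedDispersalVelocity(doubled),
               weightedDispersalVelocity(tb) / 2)
  expect_equal(weightedDiffusionCoefficient(doubled),
               weightedDiffusionCoefficient(tb) / 2)
})

test_that("wavefront series matches the brute-force scan and is monotone", {
  # stationary process: all nodes at the origin
  still <- makeTable(d = rep(0, 4), t = 1:4, startLon = 2, startLat = 1,
                     endLon = rep(2, 4), endLat = rep(1, 4),
                     projected = FALSE)
  expect_true(all(wavefrontSeries(still, c(1, 2, 3))$distance_km == 0))
  # nodes at planar distances (0, 3, 1) reached at times (0, 1, 2)
  steps <- makeTable(d = c(3, 1), t = c(1, 2), startLon = 0,
                     endLon = c(3, 1), projected = TRUE)
  expect_equal(wavefrontSeries(steps, c(1, 2),
                               origin = c(0, 0))$distance_km, c(3, 3))
  expect_error(wavefrontSeries(steps, numeric(0)), "empty")
  # brute-force oracle on a fixture table
  tb <- fixtureTables()[[1]]
  br <- branchData(tb)
  org <- c(br$startLon[which.min(br$startTime)],
           br$startLat[which.min(br$startTime)])
  grid <- seq(min(br$startTime), max(br$endTime), length.out = 23)
  got <- wavefrontSeries(tb, grid)$distance_km
  brute <- vapply(grid, function(t) {
    cand <- 0
    for (i in seq_len(nrow(br))) {
      if (br$startTime[i] <= t)
        cand <- c(cand, greatCircleDistance(org, c(br$startLon[i],
                                                   br$startLat[i])))
      if (br$endTime[i] <= t)
        cand <- c(cand, greatCircleDistance(org, c(br$endLon[i],
                                                   br$endLat[i])))
      if (br$startTime[i] <= t && br$endTime[i] > t) {
        f <- (t - br$startTime[i]) / br$duration[i]
        ip <- c(br$startLon[i] + f * (br$endLon[i] - br$startLon[i]),
                br$startLat[i] + f * (br$endLat[i] - br$startLat[i]))
        cand <- c(cand, greatCircleDistance(org, ip))
      }
    }
    max(cand)
  }, 0)
  expect_equal(got, brute, tolerance = 1e-12)
  expect_true(all(diff(got) >= 0))
  nd <- nodeData(fixtureTrees()[[1]])
  expect_lte(max(got), max(greatCircleDistance(org, cbind(nd$lon, nd$lat))))
})

test_that("isolation-by-distance signal detects exact affine structure", {
  # planar tips whose geographic distances equal patristic durations exactly
  nodes <- data.frame(id = 1:5, parent = c(NA, 1L, 2L, 2L, 1L),
                      time = c(0, 1, 2, 2, 2),
                      lon = c(0, 0, 0, 2, 1),
                      lat = c(0, 0, 0, 0, sqrt(16 - 1)),
                      label = c(NA, NA, "A", "B", "C"),
                      stringsAsFactors = FALSE)
  tr <- new("GeoTree", nodes = nodes, annotations = list(),
            mostRecentDate = 2, projected = TRUE, treeIndex = 1L)
  ibd <- ibdSignal(extractBranchTable(tr), tr)
  expect_equal(ibd$pearson, 1.0, tolerance = 1e-12)
  expect_equal(ibd$nPairs, 3L)
  # three tips: correlation equals the closed form on the 3 pairs
  pat <- patristicDurations(tr)
  nd <- nodeData(tr)
  tipRows <- which(!nd$id %in% nd$parent)
  geo <- c(sqrt(sum((nd[tipRows[1], c("lon", "lat")] -
                       nd[tipRows[2], c("lon", "lat")])^2)),
           sqrt(sum((nd[tipRows[1], c("lon", "lat")] -
                       nd[tipRows[3], c("lon", "lat")])^2)),
           sqrt(sum((nd[tipRows[2], c("lon", "lat")] -
                       nd[tipRows[3], c("lon", "lat")])^2)))
  dur <- c(pat[1, 2], pat[1, 3], pat[2, 3])
  direct <- sum((geo - mean(geo)) * (dur - mean(dur))) /
    sqrt(sum((geo - mean(geo))^2) * sum((dur - mean(dur))^2))
  expect_equal(ibd$pearson, direct, tolerance = 1e-12)
  # fewer than 3 tips is refused
  two <- data.frame(id = 1:3, parent = c(NA, 1L, 1L), time = c(0, 1, 1),
                    lon = c(0, 1, 2), lat = 0, label = c(NA, "A", "B"),
                    stringsAsFactors = FALSE)
  cherry <- new("GeoTree", nodes = two, annotations = list(),
                mostRecentDate = 1, projected = TRUE, treeIndex = 1L)
  expect_error(ibdSignal(extractBranchTable(cherry), cherry), "3 tips")
})

test_that("permuting tip locations destroys the IBD signal on average", {
  tr <- fixtureTrees()[[1]]
  set.seed(42)
  r <- replicate(200, {
    nd <- nodeData(tr)
    isTip <- !nd$id %in% nd$parent
    perm <- sample(which(isTip))
    nd$lon[isTip] <- nd$lon[perm]
    nd$lat[isTip] <- nd$lat[perm]
    p <- new("GeoTree", nodes = nd, annotations = list(),
             mostRecentDate = tr@mostRecentDate, projected = FALSE,
             treeIndex = 1L)
    ibdSignal(extractBranchTable(p), p)$pearson
  })
  expect_lt(abs(mean(r)), 0.1)
})

test_that("posterior HPD interval is the shortest window of the sorted values", {
  const <- posteriorSummary(rep(3.2, 10), 0.95)
  expect_equal(const$hpdLow, 3.2)
  expect_equal(const$hpdHigh, 3.2)
  seq100 <- posteriorSummary(1:100, 0.95)
  expect_equal(seq100$hpdHigh - seq100$hpdLow, 94)  # ceil(0.95*100) points
  # window always holds at least ceil(mass n) values (property over draws)
  set.seed(8)
  for (i in 1:20) {
    x <- rexp(sample(20:200, 1))
    mass <- runif(1, 0.5, 0.99)
    ps <- posteriorSummary(x, mass)
    expect_gte(sum(x >= ps$hpdLow & x <= ps$hpdHigh), ceiling(mass * length(x)))
  }
  expect_error(posteriorSummary(c(1, NA, 2)), "finite")
  expect_error(posteriorSummary(c(1, 2), mass = 1), "mass")
})

test_that("posterior dispersal summary assembles per-tree statistics", {
  s <- dispersalStatistics(fixtureTables(), fixtureTrees(), mass = 0.95,
                           wavefrontPoints = 20L)
  expect_equal(nrow(s@perTree), 10L)
  expect_true(all(s@perTree$wdc >= 0))
  sm <- s@summaries
  expect_true(all(sm$hpdLow <= sm$median & sm$median <= sm$hpdHigh))
  expect_true(all(diff(s@wavefront$median) >= -1e-9))
})
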