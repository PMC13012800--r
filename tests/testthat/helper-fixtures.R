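# Shared fixtures, generated once per test run.

# fixture suite directory (memoised)
fixtureDir <- local({
  dir <- NULL
  function(seed = 7L) {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), sprintf("fixtures_%d", seed))
      generateFixtureSuite(dir, seed = seed, scale = "small")
    }
    dir
  }
})

fixtureManifest <- function(seed = 7L) {
  jsonlite::fromJSON(file.path(fixtureDir(seed), "manifest.json"))
}

fixtureTrees <- local({
  trees <- NULL
  function() {
    if (is.null(trees))
      trees <<- parseAnnotatedTrees(file.path(fixtureDir(), "posterior.trees"),
                                    mostRecentSamplingDate = 2020,
                                    nToSample = 10, seed = 1)
    trees
  }
})

fixtureTables <- function() lapply(fixtureTrees(), extractBranchTable)

# hand-built GeoTree: 3 tips, caterpillar ((A,B),C), explicit coordinates
tinyTree <- function(projected = FALSE) {
  nodes <- data.frame(
    id = 1:5,
    parent = c(NA, 1L, 2L, 2L, 1L),
    time = c(2016, 2018, 2020, 2020, 2020),
    lon = c(0, 1, 2, 1.5, -1),
    lat = c(0, 0.5, 1, -0.5, 0.2),
    label = c(NA, NA, "A", "B", "C"),
    stringsAsFactors = FALSE)
  new("GeoTree", nodes = nodes, annotations = list(),
      mostRecentDate = 2020, projected = projected, treeIndex = 1L)
}

# fabricate a valid extraction table from vectors (unit-test scaffolding)
makeTable <- function(d, t, startLon = 0, startLat = 0, endLon = NULL,
                      endLat = NULL, startTime = 0, projected = TRUE) {
  n <- length(d)
  if (is.null(endLon)) endLon <- startLon + d  # planar: distance = d along x
  if (is.null(endLat)) endLat <- rep_len(startLat, n)
  br <- data.frame(node1 = rep(1L, n), node2 = seq_len(n) + 1L,
                   startTime = rep_len(startTime, n),
                   endTime = rep_len(startTime, n) + t, duration = t,
                   startLon = rep_len(startLon, n),
                   startLat = rep_len(startLat, n),
                   endLon = endLon, endLat = endLat,
                   greatCircleDistance_km = d,
                   tipFlag = rep(TRUE, n))
  phylospread:::.newExtractionTable(br, projected = projected)
}

# independent haversine for oracle checks (radius 6371 km)
oracleHaversine <- function(p1, p2) {
  toRad <- pi / 180
  dlat <- (p2[2] - p1[2]) * toRad
  dlon <- (p2[1] - p1[1]) * toRad
  a <- sin(dlat / 2)^2 + cos(p1[2] * toRad) * cos(p2[2] * toRad) *
    sin(dlon / 2)^2
  2 * 6371 * asin(sqrt(a))
}

# uniform / gradient / half-contrast study rasters used across tests
uniformRaster <- function() envRaster(matrix(1, 50, 50), -5, -5, 0.2, "uniform")
gradientRaster <- function()
  envRaster(matrix(rep(seq(0, 1, length.out = 50), each = 50), 50, 50),
            -5, -5, 0.2, "gradient")
halfRaster <- function(lowValue = 0)
  envRaster(cbind(matrix(lowValue, 50, 25), matrix(1, 50, 25)),
            -5, -5, 0.2, "half")
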