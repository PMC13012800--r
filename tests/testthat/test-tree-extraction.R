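test_that("burn-in and seeded subsampling select the right trees", {
  path <- file.path(fixtureDir(), "posterior.trees")
  trees <- parseAnnotatedTrees(path, mostRecentSamplingDate = 2020,
                               burnInFraction = 0.5, nToSample = 5, seed = 3)
  expect_length(trees, 5L)
  idx <- vapply(trees, function(t) t@treeIndex, 1L)
  expect_true(all(idx >= 6L & idx <= 10L))
  expect_false(anyDuplicated(idx) > 0)
  # same seed reproduces the draw
  trees2 <- parseAnnotatedTrees(path, mostRecentSamplingDate = 2020,
                                burnInFraction = 0.5, nToSample = 5, seed = 3)
  expect_identical(idx, vapply(trees2, function(t) t@treeIndex, 1L))
  expect_error(parseAnnotatedTrees(path, mostRecentSamplingDate = 2020,
                                   burnInFraction = 0.5, nToSample = 6),
               "post-burn-in")
})

test_that("node ages are anchored at the most recent sampling date", {
  path <- file.path(fixtureDir(), "posterior.trees")
  tr <- parseAnnotatedTrees(path, mostRecentSamplingDate = 2020,
                            nToSample = 1, seed = 1)[[1]]
  nd <- nodeData(tr)
  expect_equal(max(nd$time), 2020)
  rootAge <- max(nd$time) - nd$time[is.na(nd$parent)]
  expect_equal(nd$time[is.na(nd$parent)], 2020 - rootAge)
})

test_that("write-then-read round trip reproduces generator coordinates", {
  man <- fixtureManifest()
  trees <- parseAnnotatedTrees(file.path(fixtureDir(), "posterior.trees"),
                               mostRecentSamplingDate = 2020,
                               nToSample = 10, seed = 1)
  tr1 <- trees[[which(vapply(trees, function(t) t@treeIndex, 1L) == 1L)]]
  # node numbering is parser-assigned; align the two tables on node times
  # (continuous, almost surely distinct) before comparing coordinates
  nd <- nodeData(tr1)
  nd <- nd[order(round(nd$time, 6), nd$lon), ]
  gen <- as.data.frame(man$tree1Nodes)
  gen <- gen[order(round(gen$time, 6), gen$lon), ]
  expect_equal(nd$lon, gen$lon, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(nd$lat, gen$lat, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(nd$time, gen$time, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("extraction yields one movement vector per non-root node", {
  tb <- extractBranchTable(tinyTree())
  br <- branchData(tb)
  expect_equal(nrow(br), 4L)  # 2n - 2 for n = 3
  expect_setequal(br$node2, 2:5)
  for (tr in fixtureTrees()) {
    b <- branchData(extractBranchTable(tr))
    expect_equal(nrow(b), 2L * nTips(tr) - 2L)
    # total branch duration equals tree length
    nd <- nodeData(tr)
    len <- sum(nd$time[!is.na(nd$parent)] -
                 nd$time[match(nd$parent[!is.na(nd$parent)], nd$id)])
    expect_equal(sum(b$duration), len, tolerance = 1e-9)
    # each branch starts exactly at its parent node's location
    p <- match(b$node1, nd$id)
    expect_identical(b$startLon, nd$lon[p])
    expect_identical(b$startLat, nd$lat[p])
  }
})

test_that("branch distances match an independent haversine", {
  tr <- tinyTree()
  br <- branchData(extractBranchTable(
    new("GeoTree", nodes = tr@nodes, annotations = list(),
        mostRecentDate = 2020, projected = FALSE, treeIndex = 1L)))
  for (i in seq_len(nrow(br))) {
    expect_equal(br$greatCircleDistance_km[i],
                 oracleHaversine(c(br$startLon[i], br$startLat[i]),
                                 c(br$endLon[i], br$endLat[i])),
                 tolerance = 1e-6)
  }
  # coincident start/end -> zero distance
  nd <- tr@nodes
  nd$lon <- 3; nd$lat <- 1
  same <- new("GeoTree", nodes = nd, annotations = list(),
              mostRecentDate = 2020, projected = FALSE, treeIndex = 1L)
  expect_true(all(branchData(extractBranchTable(same))$greatCircleDistance_km
                  == 0))
})

test_that("parser rejects malformed inputs with informative errors", {
  # missing location annotation names the node
  bad <- c("#NEXUS", "Begin trees;",
           "tree STATE_0 = [&R] ((A[&location={1,2}]:1,B:1)[&location={0,0}]:1,C[&location={3,4}]:2)[&location={0,1}];",
           "End;")
  expect_error(parseAnnotatedTrees(bad, mostRecentSamplingDate = 2020),
               "tip 'B'")
  # polytomy rejected, never silently resolved
  poly <- c("#NEXUS", "Begin trees;",
            paste0("tree STATE_0 = [&R] (A[&location={1,2}]:1,",
                   "B[&location={1,2}]:1,C[&location={1,2}]:1)",
                   "[&location={0,0}];"),
            "End;")
  expect_error(parseAnnotatedTrees(poly, mostRecentSamplingDate = 2020),
               "binary")
  # mixing joint and split conventions rejected
  mixed <- c("#NEXUS", "Begin trees;",
             paste0("tree STATE_0 = [&R] (A[&location={1,2}]:1,",
                    "B[&location1=1,location2=2]:1)[&location={0,0}];"),
             "End;")
  expect_error(parseAnnotatedTrees(mixed, mostRecentSamplingDate = 2020),
               "mixes")
})

test_that("split location1/location2 annotations parse with the lat/lon swap", {
  txt <- c("#NEXUS", "Begin trees;",
           paste0("tree STATE_0 = [&R] (A[&location1=10,location2=20]:1,",
                  "B[&location1=-5,location2=7]:1)",
                  "[&location1=0,location2=1];"),
           "End;")
  tr <- parseAnnotatedTrees(txt, mostRecentSamplingDate = 2000)[[1]]
  nd <- nodeData(tr)
  a <- nd[which(nd$label == "A"), ]
  expect_equal(c(a$lon, a$lat), c(20, 10))  # lon = location2, lat = location1
})

test_that("extraction-table CSV round trips at full precision", {
  tb <- extractBranchTable(tinyTree())
  f <- tempfile(fileext = ".csv")
  writeExtractionTable(tb, f)
  back <- readExtractionTable(f, mostRecentDate = 2020)
  expect_identical(branchData(back), branchData(tb))
  # extreme coordinates survive exactly
  ext <- makeTable(d = c(10, 20), t = c(1, 2), startLon = -180,
                   endLon = c(180, 179.999999999), endLat = c(89.5, -89.5),
                   projected = FALSE)
  writeExtractionTable(ext, f)
  expect_identical(branchData(readExtractionTable(f)), branchData(ext))
  # empty table -> header-only CSV
  empty <- phylospread:::.newExtractionTable(branchData(tb)[0, ])
  writeExtractionTable(empty, f)
  expect_identical(readLines(f)[1],
                   paste(phylospread:::.BRANCH_COLUMNS, collapse = ","))
  expect_equal(nrow(branchData(readExtractionTable(f))), 0L)
  # malformed row reported with its position
  writeLines(c(readLines(f)[1], "1,2,0,oops,1,0,0,1,1,5,TRUE"), f)
  expect_error(readExtractionTable(f), "row 1")
  # randomised metadata header round trips
  rnd <- randomizeTable(tb, uniformRaster(), seed = 1)
  writeExtractionTable(rnd, f)
  expect_true(readVector <- readExtractionTable(f)@randomised)
})

test_that("near-zero branch durations are clamped and flagged", {
  nd <- tinyTree()@nodes
  nd$time[4] <- nd$time[2] + 1e-12  # almost zero-length branch
  tr <- new("GeoTree", nodes = nd, annotations = list(),
            mostRecentDate = 2020, projected = FALSE, treeIndex = 1L)
  tb <- extractBranchTable(tr)
  expect_length(tb@flags$clamped, 1L)
  expect_true(all(branchData(tb)$duration >= 1e-8))
})

test_that("tip subsampling collapses unobserved paths into net displacements", {
  tr <- fixtureTrees()[[1]]
  keep <- sort(tipLabels(tr))[1:8]
  sub <- subsampleTips(tr, keep)
  expect_equal(nTips(sub), 8L)
  expect_setequal(tipLabels(sub), keep)
  expect_equal(nrow(branchData(extractBranchTable(sub))), 14L)  # 2n - 2
  # kept tips retain their exact coordinates and times
  ndF <- nodeData(tr); ndS <- nodeData(sub)
  for (lb in keep) {
    expect_identical(ndS$lon[which(ndS$label == lb)],
                     ndF$lon[which(ndF$label == lb)])
    expect_identical(ndS$time[which(ndS$label == lb)],
                     ndF$time[which(ndF$label == lb)])
  }
})

test_that("patristic durations agree with the ape cophenetic oracle", {
  tr <- fixtureTrees()[[2]]
  mine <- patristicDurations(tr)
  phy <- asPhylo(tr)
  ref <- ape::cophenetic.phylo(phy)[rownames(mine), colnames(mine)]
  expect_equal(unname(mine), unname(ref), tolerance = 1e-9)
})
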