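#' @include simulators.R tree-io.R raster.R
NULL

#' Generate the synthetic fixture suite
#'
#' Writes everything needed to exercise the full toolbox without external
#' data: an annotated-NEXUS posterior of simulated trees (birth-death
#' topologies with Brownian dispersal, shared tip label set), an MCC-style
#' summary tree whose internal nodes carry square 80% HPD polygon
#' annotations, four ESRI ASCII rasters (uniform, west-east linear
#' gradient, half-plane barrier, seeded random noise) and a JSON manifest
#' recording every generating parameter plus the exact node coordinates of
#' the first tree (the round-trip oracle). Regenerating with the same seed
#' is byte-identical.
#'
#' Default study conditions: `small` writes 10 trees of 20 tips, the
#' default scale 100 trees of 50 tips; Yule rate 1/yr, per-axis variance
#' rate 200 km2/yr (diffusion coefficient 100 km2/yr, a mid-range value for
#' a regional outbreak), most recent tip at 2020.0, rasters of 50 x 50
#' cells of 0.2 degrees centred on the root at (0, 0).
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed.
#' @param scale `"small"` or `"default"`.
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
generateFixtureSuite <- function(outDir, seed = 1L, scale = c("small",
                                                              "default")) {
  scale <- match.arg(scale)
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", outDir)
  nTrees <- if (scale == "small") 10L else 100L
  nTips <- if (scale == "small") 20L else 50L
  sigma2 <- 200; lambda <- 1; mrd <- 2020.0
  trees <- lapply(seq_len(nTrees), function(i) {
    cfg <- simulationConfig(seed = (seed * 1000L + i) %% 2147483647L,
                            mode = "BRW", sigma2 = sigma2, lambda = lambda,
                            mu = 0, stopTipCount = nTips,
                            rootLocation = c(0, 0))
    tr <- simulateBirthDeathDiffusion(cfg)$tree
    nd <- tr@nodes
    isTip <- !nd$id %in% nd$parent
    nd$label[isTip] <- paste0("t", seq_len(sum(isTip)))  # shared taxon set
    nd$time <- nd$time - max(nd$time) + mrd
    new("GeoTree", nodes = nd, annotations = list(), mostRecentDate = mrd,
        projected = FALSE, treeIndex = i)
  })
  posteriorPath <- file.path(outDir, "posterior.trees")
  writeAnnotatedNexus(trees, posteriorPath)

  # MCC-style tree: first sample, square 80% HPD polygons around each
  # internal node (side 1 degree)
  mcc <- trees[[1]]
  nd <- mcc@nodes
  ann <- list()
  half <- 0.5
  for (id in nd$id[nd$id %in% nd$parent]) {
    i <- match(id, nd$id)
    ann[[as.character(id)]] <- list(
      `location1_80%HPD_1` = nd$lat[i] + half * c(-1, -1, 1, 1, -1),
      `location2_80%HPD_1` = nd$lon[i] + half * c(-1, 1, 1, -1, -1))
  }
  mcc@annotations <- ann
  mccPath <- file.path(outDir, "mcc.tree")
  writeAnnotatedNexus(mcc, mccPath)

  nr <- 50L; nc <- 50L; cs <- 0.2; xll <- -5; yll <- -5
  uniform <- envRaster(matrix(1, nr, nc), xll, yll, cs, "uniform")
  gradient <- envRaster(matrix(rep(seq(0, 1, length.out = nc), each = nr),
                               nr, nc), xll, yll, cs, "gradient")
  barrier <- {
    m <- matrix(1, nr, nc)
    m[, seq_len(nc %/% 2)] <- NA  # western half-plane masked
    envRaster(m, xll, yll, cs, "barrier")
  }
  set.seed(seed)
  noise <- envRaster(matrix(stats::runif(nr * nc), nr, nc), xll, yll, cs,
                     "noise")
  rasterPaths <- vapply(list(uniform, gradient, barrier, noise), function(r) {
    p <- file.path(outDir, paste0(r@name, ".asc"))
    writeEnvRaster(r, p)
    p
  }, "")

  manifest <- list(
    seed = seed, scale = scale, nTrees = nTrees, nTips = nTips,
    sigma2 = sigma2, trueD = sigma2 / 2, lambda = lambda,
    mostRecentSamplingDate = mrd,
    raster = list(nrow = nr, ncol = nc, cellSize = cs, xll = xll, yll = yll),
    files = list(posterior = basename(posteriorPath), mcc = basename(mccPath),
                 rasters = basename(rasterPaths)),
    tree1Nodes = trees[[1]]@nodes[, c("id", "parent", "time", "lon", "lat")])
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       na = "null")
  invisible(manifest)
}
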