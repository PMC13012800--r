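#' @import methods
NULL

# required column set of the per-branch movement-vector table
.BRANCH_COLUMNS <- c("node1", "node2", "startTime", "endTime", "duration",
                     "startLon", "startLat", "endLon", "endLat",
                     "greatCircleDistance_km", "tipFlag")

# durations below this are clamped (and flagged) so velocity/diffusion
# ratios stay finite
.MIN_DURATION <- 1e-8

#' Time-scaled rooted binary tree with node coordinates
#'
#' A `GeoTree` holds one posterior sample from a continuous phylogeographic
#' reconstruction: a rooted, strictly binary, time-scaled tree whose every
#' node (tips and internal nodes alike) carries a 2-D location. Node times
#' are calendar times in decimal years, anchored so that the most recent tip
#' sits at `mostRecentDate`.
#'
#' @slot nodes data.frame with columns `id` (integer, unique), `parent`
#'   (integer, `NA` for the root), `time` (calendar time, decimal years),
#'   `lon`, `lat` (decimal degrees, or projected km when `projected` is
#'   `TRUE`) and `label` (tip label, `NA` for internal nodes).
#' @slot annotations named list keyed by node id (as character); each element
#'   is a named list of annotation values parsed from the tree file.
#' @slot mostRecentDate calendar time (decimal year) of the most recent tip.
#' @slot projected `TRUE` when coordinates are planar (km) rather than
#'   geographic degrees; propagated to every downstream distance computation.
#' @slot treeIndex index of this sample in the posterior file (NA if unknown).
#'
#' @seealso [parseAnnotatedTrees()], [extractBranchTable()]
#' @export
setClass("GeoTree",
         representation(nodes = "data.frame",
                        annotations = "list",
                        mostRecentDate = "numeric",
                        projected = "logical",
                        treeIndex = "integer"))

setValidity("GeoTree", function(object) {
  nd <- object@nodes
  need <- c("id", "parent", "time", "lon", "lat", "label")
  if (!all(need %in% names(nd)))
    return(paste("nodes must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(nd$id)) return("duplicate node ids")
  root <- which(is.na(nd$parent))
  if (length(root) != 1L) return("tree must have exactly one root")
  if (!all(nd$parent[-root] %in% nd$id)) return("parent ids must exist")
  kids <- table(factor(nd$parent[!is.na(nd$parent)], levels = nd$id))
  if (!all(kids %in% c(0L, 2L)))
    return("tree must be strictly binary (every internal node has 2 children)")
  if (!all(is.finite(nd$time))) return("node times must be finite")
  if (!all(is.finite(nd$lon)) || !all(is.finite(nd$lat)))
    return("node coordinates must be finite")
  pt <- nd$time[match(nd$parent, nd$id)]
  ok <- is.na(pt) | (nd$time >= pt - 1e-9)
  if (!all(ok)) return("child calendar times must not precede parent times")
  TRUE
})

#' Per-branch movement-vector table
#'
#' The universal intermediate of all analyses: one row per phylogenetic
#' branch, each branch summarised as a movement vector with start/end
#' calendar times, start/end locations, duration and great-circle distance.
#' A binary rooted tree with n tips yields exactly 2n-2 rows (the root
#' contributes no row).
#'
#' @slot branches data.frame with columns `node1` (parent id), `node2`
#'   (child id), `startTime`, `endTime`, `duration` (decimal years),
#'   `startLon`, `startLat`, `endLon`, `endLat`,
#'   `greatCircleDistance_km` and `tipFlag` (child is a tip).
#' @slot treeIndex posterior sample index this table was extracted from.
#' @slot mostRecentDate calendar time of the most recent tip.
#' @slot projected `TRUE` for planar coordinates (distances then Euclidean km).
#' @slot randomised `TRUE` when produced by [randomizeTable()].
#' @slot flags list of bookkeeping: `clamped` (row indices whose duration was
#'   clamped to 1e-8), `fallback` (rows where randomisation kept the observed
#'   bearing after exhausting retries).
#'
#' @export
setClass("ExtractionTable",
         representation(branches = "data.frame",
                        treeIndex = "integer",
                        mostRecentDate = "numeric",
                        projected = "logical",
                        randomised = "logical",
                        flags = "list"))

setValidity("ExtractionTable", function(object) {
  br <- object@branches
  if (!all(.BRANCH_COLUMNS %in% names(br)))
    return(paste("branches must have columns:",
                 paste(.BRANCH_COLUMNS, collapse = ", ")))
  if (nrow(br) == 0L) return(TRUE)
  if (anyDuplicated(br$node2)) return("node2 ids must be unique")
  if (any(br$duration <= 0)) return("durations must be positive")
  if (any(br$startTime >= br$endTime)) return("startTime must precede endTime")
  if (any(br$greatCircleDistance_km < 0)) return("distances must be >= 0")
  TRUE
})

#' Georeferenced environmental raster
#'
#' A single-band regular grid of environmental values. Cells are half-open
#' squares; the value applies to the whole cell. Missing data are `NA`.
#' Row 1 of the value matrix is the northernmost row (ESRI ASCII layout).
#'
#' @slot values numeric matrix, row 1 = top (north).
#' @slot xll,yll coordinates of the lower-left corner of the grid.
#' @slot cellSize side length of a cell in coordinate units (degrees).
#' @slot name raster name used in result tables.
#'
#' @seealso [envRaster()], [readEnvRaster()], [rescaleRaster()]
#' @export
setClass("EnvRaster",
         representation(values = "matrix",
                        xll = "numeric", yll = "numeric",
                        cellSize = "numeric", name = "character"))

setValidity("EnvRaster", function(object) {
  if (!is.numeric(object@values)) return("values must be numeric")
  if (length(object@cellSize) != 1L || object@cellSize <= 0)
    return("cellSize must be a single positive number")
  if (!any(is.finite(object@values))) return("raster needs >= 1 non-missing cell")
  TRUE
})

#' A single credible-region polygon layer
#'
#' One highest-posterior-density region: a set of rings (closed polygons) in
#' lon/lat together with the credibility mass it encloses. Regions built by
#' [kdeHpdRegion()] additionally keep the density grid and threshold so that
#' point membership can be evaluated exactly as the set of grid cells above
#' the threshold.
#'
#' @slot label region label (node id or slice identifier).
#' @slot mass credibility mass in (0, 1).
#' @slot rings list of closed 2-column (lon, lat) matrices.
#' @slot sliceEnd upper calendar-time bound of the time slice (NA otherwise).
#' @slot grid list with `x`, `y`, `z` (KDE grid) and `threshold`, or empty.
#' @slot flagged TRUE for degenerate inputs (all points identical).
#' @export
setClass("HPDRegion",
         representation(label = "character", mass = "numeric",
                        rings = "list", sliceEnd = "numeric",
                        grid = "list", flagged = "logical"))

setValidity("HPDRegion", function(object) {
  if (object@mass <= 0 || object@mass >= 1) return("mass must be in (0,1)")
  for (r in object@rings) {
    if (!is.matrix(r) || ncol(r) != 2L) return("rings must be 2-column matrices")
    if (nrow(r) < 4L) return("rings need >= 4 points (closed)")
    if (any(r[1L, ] != r[nrow(r), ])) return("rings must be closed")
  }
  TRUE
})

#' Collection of credible-region layers
#'
#' @slot regions list of [HPDRegion-class] objects.
#' @slot metadata list (e.g. slice boundaries, warnings).
#' @export
setClass("HPDRegionSet",
         representation(regions = "list", metadata = "list"))

#' Randomisation-based support for a landscape statistic
#'
#' Holds the per-posterior-tree observed statistic, the matched
#' randomisation-null statistic, the fraction `p` of trees in which the
#' observation beats the null, and the Bayes-factor-style posterior odds
#' `BF = p / (1 - p)`. `p = 1` is reported with BF capped at
#' `(nTrees - 0.5) / 0.5` (an exhausted-sample sentinel).
#'
#' @slot statObs,statNull per-tree statistic values (matched one-to-one).
#' @slot p fraction of trees where the observed statistic beats its null.
#' @slot bf posterior odds p/(1-p), capped when p = 1.
#' @slot direction "positive" or "negative" (which tail was tested).
#' @slot nTrees number of posterior trees contributing.
#' @slot degenerate TRUE when observed and null statistics are identical.
#' @export
setClass("TestSupport",
         representation(statObs = "numeric", statNull = "numeric",
                        p = "numeric", bf = "numeric",
                        direction = "character", nTrees = "integer",
                        degenerate = "logical"))

setValidity("TestSupport", function(object) {
  if (object@p < 0 || object@p > 1) return("p must lie in [0,1]")
  if (object@bf < 0) return("BF must be >= 0")
  TRUE
})

#' Result of a diffusion-coefficient or isolation-by-resistance test
#'
#' For one raster and one rescaling strength k: the per-tree determination
#' coefficients under the environmental and the uniform (null) raster, their
#' difference Q, and the randomisation support.
#'
#' @slot rasterName name of the raster tested.
#' @slot k rescaling strength used ([rescaleRaster()]).
#' @slot model path model ("straight", "leastcost" or "resistance").
#' @slot perTree data.frame with columns `tree`, `r2Env`, `r2Null`, `q`,
#'   `qNull` (Q of the matched randomised table).
#' @slot support [TestSupport-class] comparing observed vs randomised Q.
#' @export
setClass("QStatResult",
         representation(rasterName = "character", k = "numeric",
                        model = "character", perTree = "data.frame",
                        support = "TestSupport"))

#' Posterior summary of lineage dispersal statistics
#'
#' @slot perTree data.frame of per-posterior-tree statistics (one row per
#'   sampled tree): weighted lineage dispersal velocity (km/yr), weighted
#'   diffusion coefficient (km2/yr), coefficient of variation of the
#'   per-branch diffusion coefficients, and isolation-by-distance
#'   correlations.
#' @slot summaries data.frame with `statistic`, `median`, `hpdLow`, `hpdHigh`.
#' @slot wavefront data.frame with `time`, `median`, `hpdLow`, `hpdHigh`
#'   (maximal wavefront distance from the origin, km).
#' @slot mass credibility mass used for the HPD summaries.
#' @export
setClass("DispersalStatsSummary",
         representation(perTree = "data.frame", summaries = "data.frame",
                        wavefront = "data.frame", mass = "numeric"))
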