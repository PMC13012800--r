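#' @include AllClasses.R distances.R dispersal-stats.R
NULL

# randomisation support: p = fraction of winning trees, BF = p/(1-p) with
# ties counted as failures and p = 1 reported via a capped sentinel
.makeSupport <- function(statObs, statNull, wins, direction = "positive",
                         degenerate = FALSE) {
  n <- length(wins)
  p <- mean(wins)
  bf <- if (p == 1) (n - 0.5) / 0.5 else p / (1 - p)
  new("TestSupport", statObs = statObs, statNull = statNull, p = p, bf = bf,
      direction = direction, nTrees = as.integer(n), degenerate = degenerate)
}

# R-squared of the univariate OLS (with intercept) of y on x; identical
# regressors on both sides of a Q difference then cancel exactly
.r2 <- function(y, x) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(0)
  stats::cor(y[ok], x[ok])^2
}

.branchEnvDistances <- function(table, raster, model) {
  br <- table@branches
  envDistance(raster, cbind(br$startLon, br$startLat),
              cbind(br$endLon, br$endLat), model = model,
              projected = table@projected)
}

#' Diffusion-coefficient (Q statistic) landscape test
#'
#' Tests whether an environmental raster explains heterogeneity in lineage
#' diffusion. For each posterior tree and each rescaling strength k, branch
#' durations are regressed on the per-branch environmental distance
#' computed on the rescaled raster (R2_env) and on the uniform k = 0 raster
#' (R2_null, i.e. plain geographic distance); the statistic is
#' `Q = R2_env - R2_null`. Support is evaluated against matched
#' branch-randomised tables: by default a tree counts as a win when
#' `Q_obs > 0` and `Q_obs > Q_null`, `p` is the winning fraction and
#' `BF = p/(1-p)`.
#'
#' @param tables list of observed [ExtractionTable-class] (one per
#'   posterior tree).
#' @param nullTables matched list of randomised tables
#'   ([randomizeTable()]), same length and order.
#' @param raster the raw environmental [EnvRaster-class].
#' @param kLadder rescaling strengths (default 10, 100, 1000).
#' @param model path model for the environmental distances.
#' @param asResistance rescaling convention passed to [rescaleRaster()].
#' @param requirePositiveQ require `Q_obs > 0` in addition to beating the
#'   null (default TRUE; set FALSE for the pure pairwise comparison).
#' @return list of [QStatResult-class], one per k.
#' @export
diffusionTest <- function(tables, nullTables, raster,
                          kLadder = c(10, 100, 1000),
                          model = c("straight", "leastcost", "resistance"),
                          asResistance = TRUE, requirePositiveQ = TRUE) {
  model <- match.arg(model)
  if (length(tables) != length(nullTables))
    stop("observed and null tables must be matched one-to-one")
  uniform <- rescaleRaster(raster, 0)
  dGeoObs <- lapply(tables, .branchEnvDistances, raster = uniform,
                    model = model)
  dGeoNull <- lapply(nullTables, .branchEnvDistances, raster = uniform,
                     model = model)
  lapply(kLadder, function(k) {
    env <- rescaleRaster(raster, k, asResistance = asResistance)
    perTree <- do.call(rbind, lapply(seq_along(tables), function(i) {
      qOf <- function(tb, dGeo) {
        dEnv <- .branchEnvDistances(tb, env, model)
        t <- tb@branches$duration
        if (!any(is.finite(dEnv))) stop("all environmental distances infinite")
        if (sum(is.finite(dEnv)) < 3L) {
          warning(sprintf("tree %d: fewer than 3 finite distances; skipped", i))
          return(c(NA_real_, NA_real_, NA_real_))
        }
        r2e <- .r2(t, dEnv); r2n <- .r2(t, dGeo)
        c(r2e, r2n, r2e - r2n)
      }
      o <- qOf(tables[[i]], dGeoObs[[i]])
      nl <- qOf(nullTables[[i]], dGeoNull[[i]])
      data.frame(tree = i, r2Env = o[1], r2Null = o[2], q = o[3],
                 qNull = nl[3])
    }))
    perTree <- perTree[stats::complete.cases(perTree), , drop = FALSE]
    wins <- perTree$q > perTree$qNull
    if (requirePositiveQ) wins <- wins & perTree$q > 0
    new("QStatResult", rasterName = raster@name, k = k, model = model,
        perTree = perTree,
        support = .makeSupport(perTree$q, perTree$qNull, wins))
  })
}

#' Dispersal-location landscape test
#'
#' Tests whether lineages preferentially circulate in (attraction) or avoid
#' (repulsion) particular environmental conditions. The per-tree statistic
#' is the mean raster value at branch end-node positions; it is compared
#' against the matched randomised tables in both directions.
#'
#' @param tables,nullTables matched lists of [ExtractionTable-class].
#' @param raster environmental [EnvRaster-class] (raw values).
#' @return list with elements `attraction` and `repulsion`, each a
#'   [TestSupport-class].
#' @export
locationTest <- function(tables, nullTables, raster) {
  stat <- function(tb) {
    v <- envValuesOnBranches(raster, tb, where = "nodes")
    if (mean(is.na(v)) > 0.5)
      stop("more than 50% of branch end nodes fall on masked cells")
    mean(v, na.rm = TRUE)
  }
  eObs <- vapply(tables, stat, 0)
  eNull <- vapply(nullTables, stat, 0)
  degenerate <- all(eObs == eNull)
  list(attraction = .makeSupport(eObs, eNull, eObs > eNull, "positive",
                                 degenerate),
       repulsion = .makeSupport(eObs, eNull, eObs < eNull, "negative",
                                degenerate))
}

# tip-pair data shared by the IBR test: positions from the table's tip rows,
# patristic durations from the tree, aligned by node id
.tipPairData <- function(tree, table) {
  nd <- tree@nodes
  tipRows <- which(!nd$id %in% nd$parent)
  pat <- patristicDurations(tree)
  br <- table@branches
  tipBr <- match(nd$id[tipRows], br$node2)
  if (anyNA(tipBr)) stop("table and tree tips do not match")
  pts <- cbind(br$endLon[tipBr], br$endLat[tipBr])
  n <- length(tipRows)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  list(p1 = pts[ij[, 1], , drop = FALSE], p2 = pts[ij[, 2], , drop = FALSE],
       dur = pat[ij])
}

#' Isolation-by-resistance landscape test
#'
#' Tests whether environmental distances explain the spatial structuring of
#' tips better than plain geographic distance (a deviation from isolation
#' by distance). For each tree and k: `r_env` is the Pearson correlation
#' between tip-pair patristic durations and tip-pair environmental
#' distances on the rescaled raster, `r_geo` the same on the uniform
#' raster, and `Q_IBR = r_env^2 - r_geo^2`; support against the matched
#' randomised tables as in [diffusionTest()].
#'
#' @param tables,nullTables matched lists of [ExtractionTable-class].
#' @param trees matched list of [GeoTree-class] (patristic durations; >= 4
#'   tips each).
#' @param raster environmental [EnvRaster-class].
#' @param model `"leastcost"` or `"resistance"`.
#' @param kLadder rescaling strengths.
#' @param asResistance rescaling convention.
#' @param requirePositiveQ as in [diffusionTest()].
#' @return list of [QStatResult-class], one per k.
#' @export
ibrTest <- function(tables, nullTables, trees, raster,
                    model = c("leastcost", "resistance"),
                    kLadder = c(10, 100, 1000), asResistance = TRUE,
                    requirePositiveQ = TRUE) {
  model <- match.arg(model)
  if (length(tables) != length(nullTables) ||
      length(tables) != length(trees))
    stop("tables, nullTables and trees must be matched one-to-one")
  if (any(vapply(trees, nTips, 0L) < 4L)) stop("need at least 4 tips")
  uniform <- rescaleRaster(raster, 0)
  pairsObs <- lapply(seq_along(tables), function(i)
    .tipPairData(trees[[i]], tables[[i]]))
  pairsNull <- lapply(seq_along(tables), function(i)
    .tipPairData(trees[[i]], nullTables[[i]]))
  proj <- tables[[1]]@projected
  lapply(kLadder, function(k) {
    env <- rescaleRaster(raster, k, asResistance = asResistance)
    qOf <- function(pd) {
      dEnv <- envDistance(env, pd$p1, pd$p2, model = model, projected = proj)
      dGeo <- envDistance(uniform, pd$p1, pd$p2, model = model,
                          projected = proj)
      re <- .r2(pd$dur, dEnv); rg <- .r2(pd$dur, dGeo)
      re - rg
    }
    q <- vapply(pairsObs, qOf, 0)
    qNull <- vapply(pairsNull, qOf, 0)
    wins <- q > qNull
    if (requirePositiveQ) wins <- wins & q > 0
    perTree <- data.frame(tree = seq_along(q), r2Env = NA_real_,
                          r2Null = NA_real_, q = q, qNull = qNull)
    new("QStatResult", rasterName = raster@name, k = k, model = model,
        perTree = perTree, support = .makeSupport(q, qNull, wins))
  })
}

#' Environmental-distance multidimensional scaling of tip locations
#'
#' Computes all pairwise environmental distances between points under the
#' chosen path model on the rescaled raster, then applies classical (metric)
#' MDS (double-centring + eigendecomposition) and returns the two leading
#' coordinates scaled by the square roots of their eigenvalues. On exactly
#' Euclidean input the configuration is recovered up to rigid motion. The
#' transformed space can be fed back into a continuous phylogeographic
#' reconstruction as a prior-informed deformation of geography.
#'
#' @param points n x 2 matrix of (lon, lat) tip locations (>= 3 distinct).
#' @param raster environmental [EnvRaster-class].
#' @param model path model for the pairwise distances.
#' @param kScaler rescaling strength applied before measuring distances.
#' @param asResistance rescaling convention.
#' @param projected treat coordinates as planar km.
#' @return n x 2 matrix of transformed coordinates with attributes
#'   `"distanceCorrelation"` (Pearson r between output Euclidean and input
#'   environmental distances) and `"eigenvalues"`.
#' @export
mdsTransform <- function(points, raster, model = c("leastcost", "straight",
                                                   "resistance"),
                         kScaler = 10, asResistance = TRUE,
                         projected = FALSE) {
  model <- match.arg(model)
  points <- rbind(points)
  if (nrow(unique(points)) < 3L) stop("need at least 3 distinct points")
  env <- rescaleRaster(raster, kScaler, asResistance = asResistance)
  n <- nrow(points)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- envDistance(env, points[ij[, 1], , drop = FALSE],
                   points[ij[, 2], , drop = FALSE], model = model,
                   projected = projected)
  if (any(!is.finite(d))) stop("pairwise distances must all be finite")
  dm <- matrix(0, n, n)
  dm[cbind(ij[, 1], ij[, 2])] <- d
  dm <- dm + t(dm)
  mds <- stats::cmdscale(dm, k = 2, eig = TRUE)
  if (sum(mds$eig > 1e-12 * max(abs(mds$eig))) < 2L)
    stop("degenerate configuration: fewer than 2 positive eigenvalues")
  out <- mds$points
  dOut <- stats::dist(out)
  attr(out, "distanceCorrelation") <-
    stats::cor(as.numeric(dOut), dm[lower.tri(dm)])
  attr(out, "eigenvalues") <- mds$eig
  out
}

#' Compare diffusion regularity between two extraction tables
#'
#' The coefficient of variation (CV) of the per-branch diffusion
#' coefficients `d^2/(4t)` measures how heterogeneous — how far from a
#' homogeneous Brownian process — the lineage diffusion is; a lower CV
#' means a more regular (more Brownian) diffusion. Used to judge whether a
#' reconstruction in an environmentally transformed space is more regular
#' than in geographic space.
#'
#' @param tableA,tableB [ExtractionTable-class] objects to compare.
#' @return list with `cvA`, `cvB` and `difference` (= cvA - cvB; negative
#'   means A is the more regular diffusion).
#' @export
diffusionRegularity <- function(tableA, tableB) {
  cv <- function(tb) {
    D <- branchDiffusionCoefficients(tb)
    if (mean(D) == 0) stop("zero-mean branch diffusion coefficients")
    stats::sd(D) / mean(D)
  }
  a <- cv(tableA); b <- cv(tableB)
  list(cvA = a, cvB = b, difference = a - b)
}

#' Write landscape-test results as CSV
#'
#' One row per posterior tree and k:
#' `raster,k,model,tree,stat_obs,stat_null,Q,p,BF`.
#'
#' @param results list of [QStatResult-class] (as returned by
#'   [diffusionTest()] / [ibrTest()]).
#' @param path output CSV path.
#' @export
writeTestResults <- function(results, path) {
  rows <- do.call(rbind, lapply(results, function(r)
    data.frame(raster = r@rasterName, k = r@k, model = r@model,
               tree = r@perTree$tree, stat_obs = r@perTree$q,
               stat_null = r@perTree$qNull, Q = r@perTree$q,
               p = r@support@p, BF = r@support@bf)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
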