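#' @include AllClasses.R extraction.R raster.R geo-utils.R
NULL

#' Randomise tree branches on a raster (null dispersal model)
#'
#' Builds a null dispersal model by re-positioning the branches of an
#' extraction table on the study raster while preserving branch durations
#' exactly and branch lengths to numerical precision:
#' \describe{
#'   \item{rotation}{branches are traversed root-to-tips; each branch keeps
#'     its start at the (already randomised) end position of its parent
#'     branch, keeps its length and duration, and draws a uniform random
#'     bearing. This preserves the tree's connectivity and geometry and is
#'     the default null of the landscape tests.}
#'   \item{translation}{each branch is independently moved to a uniform
#'     random start inside the raster extent, keeping its observed bearing
#'     and length (connectivity is deliberately destroyed).}
#' }
#' A candidate endpoint must fall inside the extent on a non-masked cell;
#' under environmental weighting it is additionally accepted with
#' probability `(v/vmax)^strength` (attraction) or `(1 - v/vmax)^strength`
#' (repulsion). After `maxTries` failures the branch keeps its observed
#' bearing (rotation) or observed position (translation) and is flagged; if
#' more than 10% of branches fall back, an error advises a larger extent.
#'
#' @param table an [ExtractionTable-class] with all node positions on
#'   non-masked cells.
#' @param raster the study-area [EnvRaster-class].
#' @param scheme `"rotation"` or `"translation"`.
#' @param envWeighting `"none"`, `"attraction"` or `"repulsion"`.
#' @param strength non-negative weighting exponent.
#' @param seed integer seed.
#' @param maxTries candidate draws per branch (default 100).
#' @return an [ExtractionTable-class] with `randomised = TRUE`; fallback row
#'   indices are recorded in `flags$fallback`.
#' @export
randomizeTable <- function(table, raster, scheme = c("rotation",
                                                     "translation"),
                           envWeighting = c("none", "attraction",
                                            "repulsion"),
                           strength = 0, seed = 1L, maxTries = 100L) {
  scheme <- match.arg(scheme)
  envWeighting <- match.arg(envWeighting)
  if (strength < 0) stop("strength must be >= 0")
  br <- table@branches
  projected <- table@projected
  obs <- rasterValueAt(raster, cbind(c(br$startLon, br$endLon),
                                     c(br$startLat, br$endLat)))
  if (anyNA(obs))
    stop("observed node positions must lie on non-masked raster cells")
  vmax <- max(raster@values[is.finite(raster@values)])
  ext <- rasterExtent(raster)
  set.seed(seed)
  accept <- function(pt) {
    v <- rasterValueAt(raster, pt)
    if (is.na(v)) return(FALSE)
    if (envWeighting == "none" || strength == 0) return(TRUE)
    pr <- if (envWeighting == "attraction") (v / vmax)^strength else
      (1 - v / vmax)^strength
    stats::runif(1) < pr
  }
  fallback <- integer(0)
  if (scheme == "rotation") {
    # traversal root-to-tips so each start is the parent's randomised end
    ord <- order(br$startTime, br$endTime)
    newStart <- matrix(NA_real_, nrow(br), 2L)
    newEnd <- matrix(NA_real_, nrow(br), 2L)
    endOf <- list()  # randomised end position by node id
    rootId <- setdiff(br$node1, br$node2)
    for (i in ord) {
      startPt <- if (br$node1[i] %in% rootId)
        c(br$startLon[i], br$startLat[i]) else endOf[[as.character(br$node1[i])]]
      d <- br$greatCircleDistance_km[i]
      placed <- FALSE
      if (d == 0) { cand <- startPt; placed <- TRUE }
      if (!placed) for (try in seq_len(maxTries)) {
        cand <- .destPoint(startPt, stats::runif(1, 0, 360), d, projected)
        if (accept(cand)) { placed <- TRUE; break }
      }
      if (!placed) {
        bear <- .bearing(c(br$startLon[i], br$startLat[i]),
                         c(br$endLon[i], br$endLat[i]), projected)
        cand <- .destPoint(startPt, bear, d, projected)
        fallback <- c(fallback, i)
      }
      newStart[i, ] <- startPt
      newEnd[i, ] <- cand
      endOf[[as.character(br$node2[i])]] <- cand
    }
  } else {
    newStart <- matrix(NA_real_, nrow(br), 2L)
    newEnd <- matrix(NA_real_, nrow(br), 2L)
    for (i in seq_len(nrow(br))) {
      bear <- if (br$greatCircleDistance_km[i] > 0)
        .bearing(c(br$startLon[i], br$startLat[i]),
                 c(br$endLon[i], br$endLat[i]), projected) else 0
      d <- br$greatCircleDistance_km[i]
      placed <- FALSE
      for (try in seq_len(maxTries)) {
        st <- c(stats::runif(1, ext["xmin"], ext["xmax"]),
                stats::runif(1, ext["ymin"], ext["ymax"]))
        if (is.na(rasterValueAt(raster, st))) next
        cand <- .destPoint(st, bear, d, projected)
        if (accept(cand)) {
          newStart[i, ] <- st; newEnd[i, ] <- cand; placed <- TRUE; break
        }
      }
      if (!placed) {
        newStart[i, ] <- c(br$startLon[i], br$startLat[i])
        newEnd[i, ] <- c(br$endLon[i], br$endLat[i])
        fallback <- c(fallback, i)
      }
    }
  }
  if (length(fallback) > 0.1 * nrow(br))
    stop(sprintf(paste("no valid candidate after %d tries for %d of %d",
                       "branches; use a larger raster extent"),
                 maxTries, length(fallback), nrow(br)))
  br$startLon <- newStart[, 1]; br$startLat <- newStart[, 2]
  br$endLon <- newEnd[, 1]; br$endLat <- newEnd[, 2]
  br$greatCircleDistance_km <- .pairDist(newStart, newEnd, projected)
  .newExtractionTable(br, treeIndex = table@treeIndex,
                      mostRecentDate = table@mostRecentDate,
                      projected = projected, randomised = TRUE,
                      flags = list(fallback = fallback))
}
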