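#' @include AllClasses.R extraction.R
NULL

#' Weighted lineage dispersal velocity
#'
#' Ratio of total great-circle distance covered to total branch duration,
#' `sum(d_i) / sum(t_i)` over all branches (km/yr). Note this statistic is
#' known to depend on sampling intensity: denser tip sampling splits
#' lineages into shorter branches whose summed displacement grows, so
#' velocities from differently sampled data sets are not comparable; prefer
#' [weightedDiffusionCoefficient()] for such comparisons.
#'
#' @param table an [ExtractionTable-class]
#' @return km per year (scalar)
#' @export
weightedDispersalVelocity <- function(table) {
  br <- table@branches
  if (!nrow(br)) stop("empty extraction table")
  sum(br$greatCircleDistance_km) / sum(br$duration)
}

#' Per-branch diffusion coefficients
#'
#' `D_i = d_i^2 / (4 t_i)` for a branch of displacement `d_i` km and
#' duration `t_i` yr: the 2-D Brownian-diffusion estimator of the branch's
#' diffusivity (km2/yr).
#'
#' @param table an [ExtractionTable-class]
#' @return numeric vector, one value per branch.
#' @export
branchDiffusionCoefficients <- function(table) {
  br <- table@branches
  if (!nrow(br)) stop("empty extraction table")
  br$greatCircleDistance_km^2 / (4 * br$duration)
}

#' Weighted diffusion coefficient (WDC)
#'
#' Duration-weighted tree-level diffusion coefficient
#' `sum(d_i^2) / (4 sum(t_i))` in km2/yr. For a homogeneous 2-D Brownian
#' walk of per-axis variance rate sigma0^2 this estimates D = sigma0^2 / 2,
#' and is approximately invariant to sampling intensity (net squared
#' displacement of a collapsed path keeps the same expectation).
#'
#' @param table an [ExtractionTable-class]
#' @return km2 per year (scalar)
#' @export
weightedDiffusionCoefficient <- function(table) {
  br <- table@branches
  if (!nrow(br)) stop("empty extraction table")
  sum(br$greatCircleDistance_km^2) / (4 * sum(br$duration))
}

#' Maximal wavefront distance through time
#'
#' For each time point of `timeGrid`, the greatest distance from the origin
#' reached by any lineage up to that time: the maximum over all branch end
#' nodes already realised (endTime <= t), plus the linearly interpolated
#' position (in lon/lat) of every branch straddling t. The series is
#' non-decreasing.
#'
#' @param table an [ExtractionTable-class]
#' @param timeGrid increasing calendar times within the tree's span.
#' @param origin `c(lon, lat)`; defaults to the root location (the start
#'   location of the earliest branch).
#' @return data.frame with columns `time` and `distance_km`.
#' @export
wavefrontSeries <- function(table, timeGrid, origin = NULL) {
  if (!length(timeGrid)) stop("empty time grid")
  br <- table@branches
  if (!nrow(br)) stop("empty extraction table")
  if (is.null(origin)) {
    i0 <- which.min(br$startTime)
    origin <- c(br$startLon[i0], br$startLat[i0])
  }
  distEnd <- .pairDist(origin, cbind(br$endLon, br$endLat), table@projected)
  distStart <- .pairDist(origin, cbind(br$startLon, br$startLat),
                         table@projected)
  out <- vapply(timeGrid, function(t) {
    done <- br$endTime <= t
    cand <- c(0, distEnd[done], distStart[br$startTime <= t])
    strad <- which(br$startTime <= t & br$endTime > t)
    if (length(strad)) {
      f <- (t - br$startTime[strad]) / br$duration[strad]
      ip <- cbind(br$startLon[strad] + f * (br$endLon[strad] - br$startLon[strad]),
                  br$startLat[strad] + f * (br$endLat[strad] - br$startLat[strad]))
      cand <- c(cand, .pairDist(origin, ip, table@projected))
    }
    max(cand)
  }, 0)
  data.frame(time = timeGrid, distance_km = cummax(out))
}

#' Isolation-by-distance signal
#'
#' Measures how spatially structured the phylogeny is: over all tip pairs,
#' the correlation between geographic great-circle distance and patristic
#' duration (time separating the tips along the tree). Strong positive
#' correlation means phylogenetically close tips are geographically close.
#'
#' @param table an [ExtractionTable-class] of the same tree (supplies tip
#'   locations).
#' @param tree the [GeoTree-class] (supplies patristic durations).
#' @param log10Transform apply log10 to both distance and duration
#'   (positive pairs only) before correlating.
#' @return list with `pearson`, `spearman`, `nPairs`.
#' @export
ibdSignal <- function(table, tree, log10Transform = FALSE) {
  if (nTips(tree) < 3L) stop("need at least 3 tips")
  nd <- tree@nodes
  isTip <- !nd$id %in% nd$parent
  tipRows <- which(isTip)
  pat <- patristicDurations(tree)
  pts <- cbind(nd$lon[tipRows], nd$lat[tipRows])
  n <- length(tipRows)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  geo <- .pairDist(pts[ij[, 1], , drop = FALSE], pts[ij[, 2], , drop = FALSE],
                   tree@projected)
  dur <- pat[ij]
  if (log10Transform) {
    ok <- geo > 0 & dur > 0
    geo <- log10(geo[ok]); dur <- log10(dur[ok])
  }
  list(pearson = stats::cor(geo, dur, method = "pearson"),
       spearman = stats::cor(geo, dur, method = "spearman"),
       nPairs = length(geo))
}

#' Shortest (highest-density) posterior interval and median
#'
#' The HPD interval is the shortest contiguous window of the sorted values
#' containing `ceiling(mass * n)` of them.
#'
#' @param values numeric vector of per-tree statistics (length >= 2).
#' @param mass credibility mass in (0, 1); default 0.95.
#' @return list with `median`, `hpdLow`, `hpdHigh`.
#' @export
posteriorSummary <- function(values, mass = 0.95) {
  if (any(!is.finite(values))) stop("non-finite values")
  if (length(values) < 2L) stop("need at least 2 values")
  if (mass <= 0 || mass >= 1) stop("mass must lie in (0, 1)")
  x <- sort(values)
  n <- length(x)
  w <- ceiling(mass * n)
  starts <- seq_len(n - w + 1L)
  widths <- x[starts + w - 1L] - x[starts]
  i <- starts[which.min(widths)]
  list(median = stats::median(x), hpdLow = x[i], hpdHigh = x[i + w - 1L])
}

#' Dispersal statistics across a posterior sample
#'
#' Computes per-tree lineage dispersal statistics (weighted dispersal
#' velocity, weighted diffusion coefficient, coefficient of variation of the
#' per-branch diffusion coefficients, isolation-by-distance correlations)
#' and summarises each across the posterior as median + HPD interval.
#' Also assembles the wavefront-through-time series (median and HPD band
#' over trees, each tree measured from its own root location).
#'
#' @param tables list of [ExtractionTable-class] (one per posterior tree).
#' @param trees optional matching list of [GeoTree-class] to enable the IBD
#'   correlations.
#' @param mass HPD mass for the posterior summaries (default 0.95).
#' @param wavefrontPoints number of grid points for the wavefront series.
#' @return a [DispersalStatsSummary-class]
#' @export
dispersalStatistics <- function(tables, trees = NULL, mass = 0.95,
                                wavefrontPoints = 50L) {
  stopifnot(length(tables) >= 1L)
  perTree <- do.call(rbind, lapply(seq_along(tables), function(i) {
    tb <- tables[[i]]
    D <- branchDiffusionCoefficients(tb)
    row <- data.frame(tree = i,
                      velocity = weightedDispersalVelocity(tb),
                      wdc = weightedDiffusionCoefficient(tb),
                      cvD = stats::sd(D) / mean(D),
                      ibdPearson = NA_real_, ibdSpearman = NA_real_)
    if (!is.null(trees)) {
      ibd <- ibdSignal(tb, trees[[i]])
      row$ibdPearson <- ibd$pearson; row$ibdSpearman <- ibd$spearman
    }
    row
  }))
  stats <- setdiff(names(perTree), "tree")
  summaries <- do.call(rbind, lapply(stats, function(s) {
    v <- perTree[[s]]
    if (all(is.na(v))) return(NULL)
    ps <- if (length(v) >= 2L) posteriorSummary(v, mass) else
      list(median = v, hpdLow = v, hpdHigh = v)
    data.frame(statistic = s, median = ps$median,
               hpdLow = ps$hpdLow, hpdHigh = ps$hpdHigh)
  }))
  t0 <- min(vapply(tables, function(tb) min(tb@branches$startTime), 0))
  t1 <- max(vapply(tables, function(tb) max(tb@branches$endTime), 0))
  grid <- seq(t0, t1, length.out = wavefrontPoints)
  wf <- vapply(tables, function(tb)
    wavefrontSeries(tb, grid)$distance_km, numeric(length(grid)))
  wf <- matrix(wf, nrow = length(grid))
  wavefront <- data.frame(
    time = grid,
    median = apply(wf, 1L, stats::median),
    hpdLow = apply(wf, 1L, function(v)
      if (length(v) >= 2L) posteriorSummary(v, mass)$hpdLow else v),
    hpdHigh = apply(wf, 1L, function(v)
      if (length(v) >= 2L) posteriorSummary(v, mass)$hpdHigh else v))
  new("DispersalStatsSummary", perTree = perTree, summaries = summaries,
      wavefront = wavefront, mass = mass)
}
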