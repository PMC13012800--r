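#' @include AllClasses.R extraction.R raster.R
NULL

#' Configuration of a phylogeographic simulation
#'
#' Collects the parameters shared by the three simulators. `sigma2` is the
#' per-axis Brownian variance rate (km2/yr): a branch of duration t in BRW
#' mode has displacement variance `sigma2 * t` on each axis, so the
#' per-branch diffusion-coefficient estimator `d^2/(4t)` has expectation
#' `sigma2 / 2` (the package's pinned D - sigma2 mapping). In RRW mode each
#' branch additionally draws a mean-1 variance scaler (gamma with shape
#' `nu`, or a mean-1 lognormal), so smaller `nu` means heavier dispersal-rate
#' heterogeneity; `nu -> Inf` recovers BRW.
#'
#' @param seed integer root seed; per-branch streams are derived by stable
#'   hashing of node ids, so topology-identical runs reproduce regardless of
#'   traversal order.
#' @param mode `"BRW"` or `"RRW"`.
#' @param sigma2 per-axis variance rate, km2/yr (> 0).
#' @param nu RRW scaler shape (> 0); variance of the gamma scaler is 1/nu.
#' @param scalerDistribution `"gamma"` (default) or `"lognormal"` (mean 1).
#' @param rootLocation `c(lon, lat)` of the root.
#' @param kSim environmental effect strength for the velocity-modulated
#'   simulator (0 = no effect).
#' @param rasterType `"resistance"` (high value slows dispersal:
#'   multiplier `1/(1 + kSim v/vmax)`) or `"conductance"`
#'   (`1 + kSim v/vmax`).
#' @param lambda,mu birth and death rates (1/yr) for the birth-death
#'   simulator.
#' @param stopTipCount,stopTime stop rule: extant tip count N or time T
#'   (exactly one must be given to the birth-death simulator).
#' @param conserveDistances resample branch directions only, keeping each
#'   branch's observed displacement magnitude (needs a located input tree).
#' @param rejectionCap max resamples per branch when a raster masks the
#'   candidate endpoint (default 1000).
#' @return a validated list of class `"simulationConfig"`.
#' @export
simulationConfig <- function(seed = 1L, mode = c("BRW", "RRW"), sigma2 = 1,
                             nu = 1, scalerDistribution = c("gamma",
                                                            "lognormal"),
                             rootLocation = c(0, 0), kSim = 0,
                             rasterType = c("resistance", "conductance"),
                             lambda = 1, mu = 0, stopTipCount = NULL,
                             stopTime = NULL, conserveDistances = FALSE,
                             rejectionCap = 1000L) {
  mode <- match.arg(mode)
  scalerDistribution <- match.arg(scalerDistribution)
  rasterType <- match.arg(rasterType)
  stopifnot(sigma2 > 0, nu > 0, lambda > 0, mu >= 0, kSim >= 0)
  structure(list(seed = as.integer(seed), mode = mode, sigma2 = sigma2,
                 nu = nu, scalerDistribution = scalerDistribution,
                 rootLocation = rootLocation, kSim = kSim,
                 rasterType = rasterType, lambda = lambda, mu = mu,
                 stopTipCount = stopTipCount, stopTime = stopTime,
                 conserveDistances = conserveDistances,
                 rejectionCap = as.integer(rejectionCap)),
            class = "simulationConfig")
}

# stable 31-bit string hash for per-branch RNG streams
.hashString <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  h
}

.branchSeed <- function(rootSeed, key) {
  as.integer((((rootSeed %% 2147483647) * 69069) %% 2147483647 +
                .hashString(key)) %% 2147483647)
}

# core diffusion engine shared by all simulators; preorder traversal with a
# per-branch seeded stream; returns the tree with simulated coordinates
.simulateDiffusion <- function(tree, config, raster = NULL) {
  nd <- tree@nodes
  projected <- tree@projected
  rootRow <- which(is.na(nd$parent))
  lon <- nd$lon; lat <- nd$lat  # may hold observed locations
  obsDist <- NULL
  if (config$conserveDistances) {
    if (!all(is.finite(lon)))
      stop("conserveDistances needs a located input tree")
    parentRow <- match(nd$parent, nd$id)
    ok <- !is.na(parentRow)
    obsDist <- rep(NA_real_, nrow(nd))
    obsDist[ok] <- .pairDist(cbind(lon[parentRow[ok]], lat[parentRow[ok]]),
                             cbind(lon[ok], lat[ok]), projected)
  }
  newLon <- rep(NA_real_, nrow(nd)); newLat <- rep(NA_real_, nrow(nd))
  newLon[rootRow] <- config$rootLocation[1]
  newLat[rootRow] <- config$rootLocation[2]
  if (!is.null(raster) &&
      is.na(rasterValueAt(raster, config$rootLocation)))
    stop("root location on a masked cell or outside the raster")
  vmax <- if (!is.null(raster) && config$kSim > 0)
    max(raster@values[is.finite(raster@values)]) else NA_real_
  ord <- order(.depths(match(nd$parent, nd$id)))
  for (i in ord) {
    p <- match(nd$parent[i], nd$id)
    if (is.na(p)) next
    t <- nd$time[i] - nd$time[p]
    set.seed(.branchSeed(config$seed, paste0("b", nd$id[i])))
    psi <- if (config$mode == "BRW") 1 else
      if (config$scalerDistribution == "gamma")
        stats::rgamma(1, shape = config$nu, rate = config$nu)
      else {
        s <- sqrt(log(1 + 1 / config$nu))
        stats::rlnorm(1, meanlog = -s^2 / 2, sdlog = s)
      }
    m <- 1
    if (!is.null(raster) && config$kSim > 0) {
      v <- rasterValueAt(raster, c(newLon[p], newLat[p]))
      rel <- if (is.na(v)) 0 else v / vmax
      m <- if (config$rasterType == "resistance")
        1 / (1 + config$kSim * rel) else 1 + config$kSim * rel
    }
    sdKm <- sqrt(config$sigma2 * max(t, .MIN_DURATION) * psi * m)
    done <- FALSE
    for (try in seq_len(config$rejectionCap)) {
      if (config$conserveDistances) {
        bearing <- stats::runif(1, 0, 360)
        cand <- .destPoint(c(newLon[p], newLat[p]), bearing, obsDist[i],
                           projected)
      } else {
        d <- stats::rnorm(2, 0, sdKm)
        cand <- if (projected) c(newLon[p] + d[1], newLat[p] + d[2]) else
          c(newLon[p] + d[1] / (.KM_PER_DEG * cos(newLat[p] * pi / 180)),
            newLat[p] + d[2] / .KM_PER_DEG)
      }
      if (is.null(raster) || !is.na(rasterValueAt(raster, cand))) {
        newLon[i] <- cand[1]; newLat[i] <- cand[2]; done <- TRUE; break
      }
    }
    if (!done)
      stop(sprintf(paste("rejection cap exceeded on branch to node %d;",
                         "reduce sigma2 or widen the unmasked corridor"),
                   nd$id[i]))
  }
  nd$lon <- newLon; nd$lat <- newLat
  new("GeoTree", nodes = nd, annotations = list(),
      mostRecentDate = tree@mostRecentDate, projected = projected,
      treeIndex = tree@treeIndex)
}

#' Simulate relaxed-random-walk dispersal along a fixed tree
#'
#' Traverses a time-scaled tree root-to-tips and draws each branch's
#' displacement from an isotropic bivariate normal with per-axis variance
#' `sigma2 * t * psi` (psi = 1 for BRW, a mean-1 gamma draw for RRW).
#' Displacements are drawn in km on the local tangent plane and converted to
#' degrees (valid at regional extents). When `raster` is given, endpoints
#' landing on masked cells or outside the extent are rejection-resampled, so
#' the raster acts as a dispersal barrier.
#'
#' @param tree a [GeoTree-class]; only topology and node times are used
#'   (node coordinates are needed only for `conserveDistances`).
#' @param config a [simulationConfig()].
#' @param raster optional barrier [EnvRaster-class].
#' @return list with `tree` (located [GeoTree-class]) and `table`
#'   (its [ExtractionTable-class]).
#' @export
simulateRRWOnTree <- function(tree, config, raster = NULL) {
  sim <- .simulateDiffusion(tree, config, raster)
  list(tree = sim, table = extractBranchTable(sim))
}

#' Simulate a birth-death tree with Brownian or relaxed-random-walk dispersal
#'
#' Grows a tree under a continuous-time birth-death process (each extant
#' lineage splits at rate `lambda`, dies at rate `mu`) until either
#' `stopTipCount` extant lineages exist or `stopTime` is reached, prunes
#' extinct lineages (collapsing pass-through nodes), then simulates
#' dispersal along the surviving tree as in [simulateRRWOnTree()]. Complete
#' extinction before the stop rule triggers a retry (up to 100, then an
#' error).
#'
#' @param config a [simulationConfig()] with the birth-death fields set.
#' @param raster optional barrier [EnvRaster-class].
#' @param keepExtinct keep extinct lineages in the returned tree.
#' @return list with `tree` and `table` as in [simulateRRWOnTree()].
#' @export
simulateBirthDeathDiffusion <- function(config, raster = NULL,
                                        keepExtinct = FALSE) {
  if (is.null(config$stopTipCount) == is.null(config$stopTime))
    stop("set exactly one of stopTipCount and stopTime")
  if (!is.null(config$stopTipCount) && config$lambda <= config$mu)
    stop("stopping on tip count needs lambda > mu")
  set.seed(config$seed)
  for (attempt in seq_len(100L)) {
    nd <- .growBirthDeath(config)
    if (!is.null(nd)) break
    nd <- NULL
  }
  if (is.null(nd)) stop("total extinction in 100 consecutive attempts")
  if (!keepExtinct) {
    tips <- nd$id[!nd$id %in% nd$parent & nd$alive]
    nd <- .pruneDf(nd[, setdiff(names(nd), "alive")], tips)
  } else nd <- nd[, setdiff(names(nd), "alive")]
  tree <- new("GeoTree",
              nodes = data.frame(id = nd$id, parent = nd$parent,
                                 time = nd$time, lon = 0, lat = 0,
                                 label = nd$label, stringsAsFactors = FALSE),
              annotations = list(), mostRecentDate = max(nd$time),
              projected = FALSE, treeIndex = NA_integer_)
  simulateRRWOnTree(tree, config, raster)
}

# Gillespie birth-death; returns the node table or NULL on total extinction
.growBirthDeath <- function(config) {
  lambda <- config$lambda; mu <- config$mu
  id <- 1L; parent <- NA_integer_; time <- 0; alive <- TRUE
  nextId <- 2L; now <- 0
  repeat {
    extant <- which(alive)
    if (!length(extant)) return(NULL)
    if (!is.null(config$stopTipCount) &&
        length(extant) >= config$stopTipCount) {
      # sample tips strictly between the Nth birth and the next event, so
      # the youngest pair of tips does not sit on zero-length branches
      now <- now + stats::rexp(1, length(extant) * (lambda + mu))
      break
    }
    rate <- length(extant) * (lambda + mu)
    dt <- stats::rexp(1, rate)
    if (!is.null(config$stopTime) && now + dt >= config$stopTime) {
      now <- config$stopTime; break
    }
    now <- now + dt
    who <- extant[sample.int(length(extant), 1L)]
    if (stats::runif(1) < lambda / (lambda + mu)) {
      id <- c(id, nextId, nextId + 1L)
      parent <- c(parent, id[who], id[who])
      time <- c(time, now, now)
      alive[who] <- FALSE; alive <- c(alive, TRUE, TRUE)
      time[who] <- now   # split moment becomes the internal node's time
      nextId <- nextId + 2L
    } else {
      alive[who] <- FALSE
      time[who] <- now   # death time
    }
  }
  time[alive] <- now     # extant lineages become tips at the stop moment
  isTip <- !id %in% parent
  lab <- rep(NA_character_, length(id))
  lab[isTip & alive] <- paste0("t", id[isTip & alive])
  lab[isTip & !alive] <- paste0("x", id[isTip & !alive])
  data.frame(id = id, parent = parent, time = time, label = lab,
             alive = alive, stringsAsFactors = FALSE)
}

#' Simulate dispersal with velocity modulated by an environmental raster
#'
#' As [simulateRRWOnTree()], but each branch's variance is additionally
#' multiplied by a local factor read from the raster at the parent node's
#' position: `1/(1 + kSim v/vmax)` for resistance-type rasters (lineages
#' slow down in high-value cells) or `1 + kSim v/vmax` for conductance-type.
#' With `kSim = 0` the output is identical (same seed, same draws) to the
#' unmodulated simulator. Masked cells also act as barriers.
#'
#' @param tree a [GeoTree-class] (topology and node times).
#' @param raster the environmental [EnvRaster-class].
#' @param config a [simulationConfig()]; `kSim` and `rasterType` control the
#'   modulation.
#' @return list with `tree` and `table` as in [simulateRRWOnTree()].
#' @export
simulateEnvDependentRRW <- function(tree, raster, config) {
  sim <- .simulateDiffusion(tree, config, raster)
  list(tree = sim, table = extractBranchTable(sim))
}
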