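#' @include AllClasses.R raster.R geo-utils.R
NULL

.PATH_MODELS <- c("straight", "leastcost", "resistance")

# ---------------------------------------------------------------------------
# Raster lattice: 8-connected graph over non-masked cells. Edge attributes:
# mean of the two cell values and the great-circle distance between the two
# cell centres (Euclidean km when projected).
# ---------------------------------------------------------------------------
.latticeEdges <- function(raster, projected = FALSE) {
  v <- raster@values
  nr <- nrow(v); nc <- ncol(v)
  id <- function(r, c) (r - 1L) * nc + c
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    r1 <- seq_len(nr); c1 <- seq_len(nc)
    r1 <- r1[r1 + o[1] >= 1L & r1 + o[1] <= nr]
    c1 <- c1[c1 + o[2] >= 1L & c1 + o[2] <= nc]
    if (!length(r1) || !length(c1)) next
    g <- expand.grid(r = r1, c = c1)
    from <- c(from, id(g$r, g$c))
    to <- c(to, id(g$r + o[1], g$c + o[2]))
  }
  rcF <- cbind((from - 1L) %/% nc + 1L, (from - 1L) %% nc + 1L)
  rcT <- cbind((to - 1L) %/% nc + 1L, (to - 1L) %% nc + 1L)
  valF <- v[rcF]; valT <- v[rcT]
  ok <- is.finite(valF) & is.finite(valT)
  from <- from[ok]; to <- to[ok]
  ctrF <- .cellCentre(raster, rcF[ok, , drop = FALSE])
  ctrT <- .cellCentre(raster, rcT[ok, , drop = FALSE])
  distKm <- .pairDist(ctrF, ctrT, projected)
  list(from = from, to = to, meanVal = (valF[ok] + valT[ok]) / 2,
       distKm = distKm, nCells = nr * nc)
}

.cellId <- function(raster, pts) {
  rc <- .cellIndex(raster, pts)
  (rc[, 1] - 1L) * ncol(raster@values) + rc[, 2]
}

# straight-line "environmental distance": line integral of cell values
# along the segment, each cell contributing value x (km of segment inside).
# Crossing parameters with the grid lines are computed exactly.
.straightLineCost <- function(raster, p1, p2, projected = FALSE) {
  tot <- .pairDist(p1, p2, projected)
  if (tot == 0) return(0)
  cs <- raster@cellSize
  sVals <- c(0, 1)
  for (axis in 1:2) {
    a <- p1[axis]; b <- p2[axis]
    if (a == b) next
    orig <- if (axis == 1) raster@xll else raster@yll
    jr <- sort(c((a - orig) / cs, (b - orig) / cs))
    js <- seq(ceiling(jr[1]), floor(jr[2]))
    if (length(js)) sVals <- c(sVals, ((orig + js * cs) - a) / (b - a))
  }
  sVals <- sort(unique(pmin(pmax(sVals, 0), 1)))
  mid <- (sVals[-1] + sVals[-length(sVals)]) / 2
  pts <- cbind(p1[1] + mid * (p2[1] - p1[1]), p1[2] + mid * (p2[2] - p1[2]))
  vals <- rasterValueAt(raster, pts)
  if (anyNA(vals)) return(Inf)  # path crosses masked cells
  sum(vals * diff(sVals)) * tot
}

#' Environmental distance between points on a raster
#'
#' Three path models turn a raster into a pairwise "environmental distance":
#' \describe{
#'   \item{straight}{line integral of cell values along the straight
#'     segment (each cell's value times the km of segment inside it).}
#'   \item{leastcost}{shortest-path cost on the 8-connected lattice of
#'     non-masked cells; an edge costs the mean of its two cell values times
#'     the distance between the cell centres (diagonals are naturally longer).}
#'   \item{resistance}{commute-time distance on the same lattice viewed as a
#'     resistor network (edge conductance = 1 / mean of the two cell
#'     values): `2 * |E| * effectiveResistance`.}
#' }
#' On the uniform raster of ones all three reduce to (a monotone function
#' of) geographic distance. Disconnected points (masked barrier) yield
#' `Inf`, reported rather than thrown.
#'
#' @param raster an [EnvRaster-class] (typically from [rescaleRaster()]).
#' @param p1,p2 points `c(lon, lat)` or matching n x 2 matrices.
#' @param model one of `"straight"`, `"leastcost"`, `"resistance"`.
#' @param projected treat coordinates as planar km.
#' @return numeric vector of costs (one per point pair).
#' @export
envDistance <- function(raster, p1, p2, model = c("straight", "leastcost",
                                                  "resistance"),
                        projected = FALSE) {
  model <- match.arg(model)
  p1 <- rbind(p1); p2 <- rbind(p2)
  if (anyNA(rasterValueAt(raster, p1)) || anyNA(rasterValueAt(raster, p2)))
    stop("point on a masked cell or outside the raster extent")
  switch(model,
    straight = vapply(seq_len(nrow(p1)), function(i)
      .straightLineCost(raster, p1[i, ], p2[i, ], projected), 0),
    leastcost = .leastCostMany(raster, p1, p2, projected),
    resistance = .resistanceMany(raster, p1, p2, projected))
}

.leastCostMany <- function(raster, p1, p2, projected = FALSE) {
  ed <- .latticeEdges(raster, projected)
  g <- igraph::graph_from_edgelist(cbind(ed$from, ed$to), directed = FALSE)
  if (igraph::vcount(g) < ed$nCells)
    g <- igraph::add_vertices(g, ed$nCells - igraph::vcount(g))
  w <- ed$meanVal * ed$distKm
  c1 <- .cellId(raster, p1); c2 <- .cellId(raster, p2)
  uf <- unique(c1); ut <- unique(c2)
  dm <- igraph::distances(g, v = uf, to = ut, weights = w)
  dm[cbind(match(c1, uf), match(c2, ut))]
}

.resistanceMany <- function(raster, p1, p2, projected = FALSE) {
  ed <- .latticeEdges(raster, projected)
  conduct <- 1 / ed$meanVal
  nE <- length(ed$from)
  c1 <- .cellId(raster, p1); c2 <- .cellId(raster, p2)
  nodes <- sort(unique(c(ed$from, ed$to, c1, c2)))
  idx <- match(c(ed$from, ed$to), nodes)
  f <- idx[seq_len(nE)]; t <- idx[nE + seq_len(nE)]
  nN <- length(nodes)
  W <- Matrix::sparseMatrix(i = c(f, t), j = c(t, f),
                            x = c(conduct, conduct), dims = c(nN, nN))
  L <- Matrix::Diagonal(x = Matrix::rowSums(W)) - W
  g <- igraph::graph_from_edgelist(cbind(f, t), directed = FALSE)
  if (igraph::vcount(g) < nN) g <- igraph::add_vertices(g, nN - igraph::vcount(g))
  comp <- igraph::components(g)$membership
  u <- match(c1, nodes); v <- match(c2, nodes)
  out <- numeric(length(u))
  for (cm in unique(comp[c(u, v)])) {
    sel <- which(comp[u] == cm | comp[v] == cm)
    for (i in sel) {
      if (comp[u[i]] != comp[v[i]]) { out[i] <- Inf; next }
      out[i] <- NA  # resolved below per component
    }
  }
  todo <- which(is.na(out))
  for (cm in unique(comp[u[todo]])) {
    members <- which(comp == cm)
    if (length(members) < 2L) { out[todo[comp[u[todo]] == cm]] <- Inf; next }
    loc <- match(seq_len(nN), members)  # global -> local index
    Lc <- L[members, members, drop = FALSE]
    ground <- length(members)
    Lr <- Lc[-ground, -ground, drop = FALSE]
    fac <- Matrix::Cholesky(Matrix::forceSymmetric(Lr), LDL = FALSE)
    for (i in todo[comp[u[todo]] == cm]) {
      a <- loc[u[i]]; b <- loc[v[i]]
      if (a == b) { out[i] <- 0; next }
      rhs <- numeric(length(members) - 1L)
      if (a != ground) rhs[a] <- 1
      if (b != ground) rhs[b] <- rhs[b] - 1
      x <- as.numeric(Matrix::solve(fac, rhs))
      xa <- if (a == ground) 0 else x[a]
      xb <- if (b == ground) 0 else x[b]
      out[i] <- 2 * nE * (xa - xb)
    }
  }
  out
}

#' Environmental values along the branches of an extraction table
#'
#' @param raster an [EnvRaster-class]
#' @param table an [ExtractionTable-class]
#' @param where `"nodes"` (value at each branch's end node), `"midpoints"`
#'   (value at the segment midpoint), or `"lineSamples"` (mean over
#'   `nSamples` equidistant points along the straight segment, masked
#'   samples dropped).
#' @param nSamples number of equidistant samples for `"lineSamples"`
#'   (minimum 10).
#' @return numeric vector, one value per branch; `NA` where all sampled
#'   positions are masked (flagged via attribute `"masked"`).
#' @export
envValuesOnBranches <- function(raster, table,
                                where = c("nodes", "midpoints", "lineSamples"),
                                nSamples = 10L) {
  where <- match.arg(where)
  br <- table@branches
  out <- switch(where,
    nodes = rasterValueAt(raster, cbind(br$endLon, br$endLat)),
    midpoints = rasterValueAt(raster, cbind((br$startLon + br$endLon) / 2,
                                            (br$startLat + br$endLat) / 2)),
    lineSamples = {
      nS <- max(10L, as.integer(nSamples))
      f <- seq(0, 1, length.out = nS)
      vapply(seq_len(nrow(br)), function(i) {
        pts <- cbind(br$startLon[i] + f * (br$endLon[i] - br$startLon[i]),
                     br$startLat[i] + f * (br$endLat[i] - br$startLat[i]))
        v <- rasterValueAt(raster, pts)
        if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
      }, 0)
    })
  if (all(is.na(out))) stop("all branch positions fall on masked cells")
  attr(out, "masked") <- which(is.na(out))
  out
}
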