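#' @include AllClasses.R
NULL

# All spherical geometry in the package uses one Earth radius.
.EARTH_RADIUS_KM <- 6371
.KM_PER_DEG <- .EARTH_RADIUS_KM * pi / 180  # km per degree of latitude

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371 km. Both arguments may be
#' single points `c(lon, lat)` or 2-column matrices (vectorised, recycled).
#'
#' @param p1,p2 points as `c(lon, lat)` in decimal degrees, or n x 2 matrices.
#' @return distance(s) in km.
#' @examples
#' greatCircleDistance(c(0, 0), c(90, 0))  # a quarter meridian: 10007.54 km
#' @export
greatCircleDistance <- function(p1, p2) {
  p1 <- rbind(p1); p2 <- rbind(p2)
  if (!all(is.finite(p1)) || !all(is.finite(p2)))
    stop("non-finite coordinates")
  if (any(abs(p1[, 2]) > 90) || any(abs(p2[, 2]) > 90))
    stop("latitudes must lie in [-90, 90]")
  as.numeric(geosphere::distHaversine(p1, p2, r = .EARTH_RADIUS_KM * 1000)) / 1000
}

# distance respecting the projected flag: Euclidean km for planar inputs
.pairDist <- function(p1, p2, projected) {
  if (projected) {
    p1 <- rbind(p1); p2 <- rbind(p2)
    sqrt((p1[, 1] - p2[, 1])^2 + (p1[, 2] - p2[, 2])^2)
  } else greatCircleDistance(p1, p2)
}

# spherical destination point: from p (lon,lat) along initial bearing
# (degrees clockwise from north) for d km; planar translation when projected
.destPoint <- function(p, bearingDeg, dKm, projected = FALSE) {
  if (dKm == 0) return(p)
  if (projected) {
    b <- bearingDeg * pi / 180
    c(p[1] + dKm * sin(b), p[2] + dKm * cos(b))
  } else {
    as.numeric(geosphere::destPoint(rbind(p), bearingDeg, dKm * 1000,
                                    a = .EARTH_RADIUS_KM * 1000, f = 0))
  }
}

# initial bearing p1 -> p2, degrees in [0, 360)
.bearing <- function(p1, p2, projected = FALSE) {
  if (projected) {
    b <- atan2(p2[1] - p1[1], p2[2] - p1[2]) * 180 / pi
    (b + 360) %% 360
  } else {
    (as.numeric(geosphere::bearing(rbind(p1), rbind(p2))) + 360) %% 360
  }
}

# even-odd point-in-polygon over a list of rings (ray casting, vectorised
# over points); rings are closed 2-column (lon,lat) matrices
.pointsInRings <- function(pts, rings) {
  pts <- rbind(pts)
  inside <- rep(FALSE, nrow(pts))
  for (r in rings) {
    x <- r[, 1]; y <- r[, 2]
    n <- length(x)
    i <- seq_len(n - 1L); j <- i + 1L
    for (k in seq_along(i)) {
      xi <- x[i[k]]; yi <- y[i[k]]; xj <- x[j[k]]; yj <- y[j[k]]
      crosses <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
        (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
    }
  }
  inside
}

# shoelace area of one closed ring (coordinate units squared)
.ringArea <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}
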