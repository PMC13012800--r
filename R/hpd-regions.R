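#' @include AllClasses.R geo-utils.R
NULL

#' Kernel-density highest-posterior-density region
#'
#' Estimates a 2-D Gaussian kernel density on a regular grid (normal
#' reference, i.e. Silverman-type, diagonal bandwidth: deterministic given
#' the data) and returns the smallest set of grid cells whose enclosed
#' density mass reaches `mass`: cells are sorted by density and accumulated
#' until the target mass is enclosed, which makes regions of increasing mass
#' nested by construction. The region boundary is returned as contour rings
#' at the threshold density.
#'
#' @param points n x 2 matrix of (lon, lat) samples, n >= 10.
#' @param mass credibility mass in (0, 1); default 0.80 (the conventional
#'   node-uncertainty level).
#' @param gridResolution grid cells per axis (default 200).
#' @param label region label.
#' @return an [HPDRegion-class]; degenerate input (all points identical)
#'   yields a flagged single-cell square around the point.
#' @export
kdeHpdRegion <- function(points, mass = 0.80, gridResolution = 200L,
                         label = "region") {
  points <- rbind(points)
  if (nrow(points) < 10L) stop("need at least 10 points")
  if (mass <= 0 || mass >= 1) stop("mass must lie in (0, 1)")
  if (all(points[, 1] == points[1, 1]) && all(points[, 2] == points[1, 2])) {
    eps <- 1e-6
    ring <- cbind(points[1, 1] + eps * c(-1, 1, 1, -1, -1),
                  points[1, 2] + eps * c(-1, -1, 1, 1, -1))
    return(new("HPDRegion", label = label, mass = mass, rings = list(ring),
               sliceEnd = NA_real_, grid = list(), flagged = TRUE))
  }
  h <- c(MASS::bandwidth.nrd(points[, 1]), MASS::bandwidth.nrd(points[, 2]))
  h[h == 0] <- 1e-6
  pad <- 1.5 * h
  kd <- MASS::kde2d(points[, 1], points[, 2], h = h, n = gridResolution,
                    lims = c(range(points[, 1]) + pad[1] * c(-1, 1),
                             range(points[, 2]) + pad[2] * c(-1, 1)))
  cellArea <- diff(kd$x[1:2]) * diff(kd$y[1:2])
  dens <- as.numeric(kd$z)
  p <- dens * cellArea
  p <- p / sum(p)                     # renormalise the discretised density
  ord <- order(dens, decreasing = TRUE)
  cum <- cumsum(p[ord])
  nIn <- which(cum >= mass)[1]
  threshold <- dens[ord[nIn]]
  rings <- lapply(grDevices::contourLines(kd$x, kd$y, kd$z,
                                          levels = threshold),
                  function(cl) {
                    r <- cbind(cl$x, cl$y)
                    if (any(r[1, ] != r[nrow(r), ])) r <- rbind(r, r[1, ])
                    r
                  })
  new("HPDRegion", label = label, mass = mass, rings = rings,
      sliceEnd = NA_real_,
      grid = list(x = kd$x, y = kd$y, z = kd$z, threshold = threshold),
      flagged = FALSE)
}

#' Point membership in an HPD region
#'
#' For KDE-built regions membership is evaluated on the density grid (the
#' region is exactly the set of grid cells at or above the threshold); for
#' regions read from annotations or files the polygon rings are used
#' (even-odd rule).
#'
#' @param region an [HPDRegion-class]
#' @param pts point `c(lon, lat)` or n x 2 matrix.
#' @return logical vector.
#' @export
regionContains <- function(region, pts) {
  pts <- rbind(pts)
  g <- region@grid
  if (length(g)) {
    ix <- findInterval(pts[, 1], g$x + diff(g$x[1:2]) / 2) + 1L
    iy <- findInterval(pts[, 2], g$y + diff(g$y[1:2]) / 2) + 1L
    ok <- ix >= 1L & ix <= length(g$x) & iy >= 1L & iy <= length(g$y)
    out <- rep(FALSE, nrow(pts))
    out[ok] <- g$z[cbind(ix[ok], iy[ok])] >= g$threshold
    out
  } else {
    .pointsInRings(pts, region@rings)
  }
}

#' Area of an HPD region
#'
#' Grid-cell area above the threshold for KDE regions (consistent with
#' [regionContains()]), shoelace ring area otherwise; square coordinate
#' units.
#'
#' @param region an [HPDRegion-class]
#' @export
regionArea <- function(region) {
  g <- region@grid
  if (length(g)) {
    cellArea <- diff(g$x[1:2]) * diff(g$y[1:2])
    sum(g$z >= g$threshold) * cellArea
  } else {
    sum(vapply(region@rings, .ringArea, 0))
  }
}

#' HPD polygons for successive time slices
#'
#' Divides the time axis (earliest root to latest tip over all tables) into
#' `sliceCount` equal slices and, for each slice, pools the end locations of
#' internal-node branches from every posterior table whose end time falls in
#' the slice (cumulative mode, the default, also includes all earlier
#' slices, matching successive-snapshot map layers). Each pool is turned
#' into a KDE HPD region; slices with fewer than 10 pooled points are
#' skipped with a warning recorded in the metadata.
#'
#' @param tables list of [ExtractionTable-class] (>= 2 posterior samples).
#' @param sliceCount number of time slices (>= 1).
#' @param mass credibility mass (default 0.80).
#' @param cumulative include all earlier slices in each pool (default TRUE).
#' @param includeTips also pool tip-node locations (default FALSE).
#' @param gridResolution KDE grid resolution per axis.
#' @return an [HPDRegionSet-class]; each region's `sliceEnd` is the slice's
#'   upper calendar-time bound.
#' @export
timeSlicePolygons <- function(tables, sliceCount, mass = 0.80,
                              cumulative = TRUE, includeTips = FALSE,
                              gridResolution = 200L) {
  if (length(tables) < 2L) stop("need at least 2 posterior tables")
  if (sliceCount < 1L) stop("sliceCount must be >= 1")
  all <- do.call(rbind, lapply(tables, function(tb) tb@branches))
  if (!includeTips) all <- all[!all$tipFlag, , drop = FALSE]
  t0 <- min(vapply(tables, function(tb) min(tb@branches$startTime), 0))
  t1 <- max(vapply(tables, function(tb) max(tb@branches$endTime), 0))
  bounds <- seq(t0, t1, length.out = sliceCount + 1L)
  regions <- list(); skipped <- numeric(0)
  for (i in seq_len(sliceCount)) {
    lo <- if (cumulative) t0 else bounds[i]
    inSlice <- all$endTime >= lo &
      (all$endTime < bounds[i + 1L] | (i == sliceCount &
                                         all$endTime <= bounds[i + 1L]))
    pts <- cbind(all$endLon[inSlice], all$endLat[inSlice])
    if (nrow(pts) < 10L) {
      warning(sprintf("slice %d has %d < 10 pooled points; polygon omitted",
                      i, nrow(pts)))
      skipped <- c(skipped, i)
      next
    }
    r <- kdeHpdRegion(pts, mass = mass, gridResolution = gridResolution,
                      label = sprintf("slice_%d", i))
    r@sliceEnd <- bounds[i + 1L]
    regions <- c(regions, list(r))
  }
  new("HPDRegionSet", regions = regions,
      metadata = list(bounds = bounds, skipped = skipped,
                      cumulative = cumulative))
}

#' Extract HPD polygons annotated on an MCC tree
#'
#' Reads per-node credible-region polygons from a summary (maximum clade
#' credibility) tree annotated in the TreeAnnotator style: parallel vertex
#' arrays `<prefix>1_80%HPD_<j>` (latitudes) and `<prefix>2_80%HPD_<j>`
#' (longitudes), one pair per polygon `j`, possibly several polygons per
#' node; an un-suffixed pair is also accepted. Internal nodes without the
#' annotation are skipped with a warning.
#'
#' @param mccTree a [GeoTree-class] parsed from an annotated MCC file.
#' @param annotationPrefix annotation stem, default `"location"`.
#' @param mass credibility mass the annotations represent (default 0.80).
#' @return an [HPDRegionSet-class], one region per annotated internal node.
#' @export
mccNodePolygons <- function(mccTree, annotationPrefix = "location",
                            mass = 0.80) {
  nd <- mccTree@nodes
  internal <- nd$id[nd$id %in% nd$parent]
  regions <- list(); missing <- integer(0)
  hpdKey <- sprintf("%s%%s_%.0f%%%%HPD", annotationPrefix, mass * 100)
  latStem <- sprintf(hpdKey, "1"); lonStem <- sprintf(hpdKey, "2")
  for (id in internal) {
    a <- mccTree@annotations[[as.character(id)]]
    if (is.null(a)) { missing <- c(missing, id); next }
    keysLat <- grep(paste0("^", .escapeRe(latStem), "(_\\d+)?$"), names(a),
                    value = TRUE)
    if (!length(keysLat)) { missing <- c(missing, id); next }
    rings <- list()
    for (kl in keysLat) {
      ko <- sub(.escapeRe(latStem), lonStem, kl)
      lat <- a[[kl]]; lon <- a[[ko]]
      if (is.null(lon) || length(lat) != length(lon))
        stop(sprintf("node %d: mismatched HPD vertex arrays ('%s'/'%s')",
                     id, kl, ko))
      r <- cbind(lon, lat)
      if (any(r[1, ] != r[nrow(r), ])) r <- rbind(r, r[1, ])
      rings <- c(rings, list(r))
    }
    regions <- c(regions, list(
      new("HPDRegion", label = sprintf("node_%d", id), mass = mass,
          rings = rings, sliceEnd = NA_real_, grid = list(),
          flagged = FALSE)))
  }
  if (length(missing))
    warning(sprintf("%d internal node(s) without '%s' HPD annotations skipped",
                    length(missing), annotationPrefix))
  new("HPDRegionSet", regions = regions, metadata = list(skipped = missing))
}

.escapeRe <- function(s) gsub("([][{}()+*^$|\\\\?.%])", "\\\\\\1", s)

#' Export credible-region layers as GeoJSON
#'
#' One feature per region (MultiPolygon; each stored ring is written as its
#' own polygon) with attributes `label`, `mass` and `sliceEnd`. Coordinates
#' are written at full precision so a read-back reproduces the geometry to
#' well below 1e-9 degrees.
#'
#' @param regions an [HPDRegionSet-class]
#' @param path output path (`.geojson`).
#' @return `path`, invisibly.
#' @export
exportVectorLayers <- function(regions, path) {
  feats <- lapply(regions@regions, function(r) {
    polys <- lapply(r@rings, function(ring)
      list(lapply(seq_len(nrow(ring)), function(i) ring[i, ])))
    list(type = "Feature",
         properties = list(label = r@label, mass = r@mass,
                           sliceEnd = if (is.na(r@sliceEnd)) NULL else
                             r@sliceEnd),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  json <- jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read credible-region layers from GeoJSON
#'
#' Inverse of [exportVectorLayers()].
#'
#' @param path GeoJSON path.
#' @return an [HPDRegionSet-class]
#' @export
readVectorLayers <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  regions <- lapply(fc$features, function(f) {
    rings <- lapply(f$geometry$coordinates, function(poly)
      do.call(rbind, lapply(poly[[1]], function(pt)
        c(pt[[1]], pt[[2]]))))
    se <- f$properties$sliceEnd
    new("HPDRegion", label = f$properties$label,
        mass = f$properties$mass, rings = rings,
        sliceEnd = if (is.null(se)) NA_real_ else se,
        grid = list(), flagged = FALSE)
  })
  new("HPDRegionSet", regions = regions, metadata = list())
}
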