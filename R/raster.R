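#' @include AllClasses.R geo-utils.R
NULL

#' Construct an environmental raster
#'
#' @param values numeric matrix of cell values, row 1 = northernmost row
#'   (ESRI ASCII layout); `NA` marks missing data.
#' @param xll,yll lower-left corner of the grid.
#' @param cellSize cell side length (degrees, or km for projected data).
#' @param name raster name carried into result tables.
#' @return an [EnvRaster-class]
#' @export
envRaster <- function(values, xll = 0, yll = 0, cellSize = 1,
                      name = "raster") {
  new("EnvRaster", values = values, xll = xll, yll = yll,
      cellSize = cellSize, name = name)
}

#' Read a single-band raster
#'
#' Supports ESRI ASCII grids (`.asc`) natively. GeoTIFF files are read via
#' the `tiff` package for pixel values, with georeferencing taken from an
#' ESRI world file (`<file>.tfw`) next to the raster or from the explicit
#' `xll`/`yll`/`cellSize` arguments (plain TIFF carries no geokeys here).
#'
#' @param path file path (`.asc` or `.tif`/`.tiff`).
#' @param name raster name; defaults to the file stem.
#' @param xll,yll,cellSize georeferencing override for TIFF input.
#' @return an [EnvRaster-class]
#' @export
readEnvRaster <- function(path, name = NULL,
                          xll = NULL, yll = NULL, cellSize = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]+$", "", basename(path))
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "asc") return(.readEsriAscii(path, name))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF rasters requires the 'tiff' package")
    info <- tiff::readTIFF(path, payload = FALSE)
    isFloat <- isTRUE(info$bits.per.sample[1] == 32L)  # 32-bit = float samples
    vals <- tiff::readTIFF(path, as.is = !isFloat)
    if (length(dim(vals)) == 3L) vals <- vals[, , 1L]
    tfw <- paste0(sub("\\.[^.]+$", "", path), ".tfw")
    if (is.null(cellSize) && file.exists(tfw)) {
      w <- as.numeric(readLines(tfw))  # A D B E C F (cell, rot, rot, -cell, x0, y0)
      cellSize <- w[1]
      # world file stores the CENTRE of the top-left pixel
      xll <- w[5] - cellSize / 2
      yll <- (w[6] + cellSize / 2) - nrow(vals) * cellSize
    }
    if (is.null(cellSize))
      stop("TIFF raster needs a world file (.tfw) or explicit xll/yll/cellSize")
    return(envRaster(vals, xll = xll, yll = yll, cellSize = cellSize,
                     name = name))
  }
  stop("unsupported raster format: ", ext)
}

.readEsriAscii <- function(path, name) {
  lines <- readLines(path)
  hdr <- list(); i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nc * nr)
    stop("ESRI ASCII grid: expected ", nc * nr, " values, found ", length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  xll <- hdr$xllcorner; yll <- hdr$yllcorner
  if (is.null(xll) && !is.null(hdr$xllcenter)) xll <- hdr$xllcenter - hdr$cellsize / 2
  if (is.null(yll) && !is.null(hdr$yllcenter)) yll <- hdr$yllcenter - hdr$cellsize / 2
  envRaster(m, xll = xll, yll = yll, cellSize = hdr$cellsize, name = name)
}

#' Write a raster as an ESRI ASCII grid
#'
#' @param raster an [EnvRaster-class]
#' @param path output path (`.asc`)
#' @param noData value standing in for missing cells (default -9999).
#' @export
writeEnvRaster <- function(raster, path, noData = -9999) {
  m <- raster@values
  m[!is.finite(m)] <- noData
  hdr <- c(sprintf("ncols %d", ncol(m)),
           sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.10g", raster@xll),
           sprintf("yllcorner %.10g", raster@yll),
           sprintf("cellsize %.10g", raster@cellSize),
           sprintf("NODATA_value %g", noData))
  body <- apply(m, 1L, function(r) paste(format(r, digits = 15, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Rescale a raster into a resistance or conductance surface
#'
#' Maps raw environmental values v onto `1 + k * v / vmax` (resistance:
#' larger value = harder to cross) or `1 + k * (1 - v / vmax)` (conductance:
#' larger value = easier to cross), where vmax is the maximum over
#' non-missing cells. `k = 0` yields the uniform raster of ones, so the
#' null model is nested within the rescaling ladder.
#'
#' @param raster an [EnvRaster-class]
#' @param k non-negative rescaling strength (typical ladder: 10, 100, 1000).
#' @param asResistance if `FALSE`, treat values as conductance.
#' @return rescaled [EnvRaster-class]
#' @export
rescaleRaster <- function(raster, k, asResistance = TRUE) {
  if (k < 0) stop("k must be >= 0")
  v <- raster@values
  out <- v
  out[is.finite(v)] <- 1
  if (k > 0) {
    vmax <- max(v[is.finite(v)])
    if (vmax <= 0) stop("vmax must be positive to rescale with k > 0")
    rel <- v[is.finite(v)] / vmax
    out[is.finite(v)] <- if (asResistance) 1 + k * rel else 1 + k * (1 - rel)
  }
  envRaster(out, xll = raster@xll, yll = raster@yll,
            cellSize = raster@cellSize,
            name = sprintf("%s_k%g", raster@name, k))
}

# --- cell indexing -----------------------------------------------------------
# Half-open cells; points map by floor indexing from the lower-left origin.
# Returns matrix row (top-down) and column; NA outside the extent.
.cellIndex <- function(raster, pts) {
  pts <- rbind(pts)
  nr <- nrow(raster@values); nc <- ncol(raster@values)
  col <- floor((pts[, 1] - raster@xll) / raster@cellSize) + 1
  rowB <- floor((pts[, 2] - raster@yll) / raster@cellSize) + 1
  # points exactly on the top/right edge belong to the last cell
  col[pts[, 1] == raster@xll + nc * raster@cellSize] <- nc
  rowB[pts[, 2] == raster@yll + nr * raster@cellSize] <- nr
  bad <- col < 1 | col > nc | rowB < 1 | rowB > nr
  col[bad] <- NA; rowB[bad] <- NA
  cbind(row = nr - rowB + 1, col = col)
}

# cell centre coordinates for (row, col) matrix indices
.cellCentre <- function(raster, rc) {
  rc <- rbind(rc)
  nr <- nrow(raster@values)
  cbind(lon = raster@xll + (rc[, 2] - 0.5) * raster@cellSize,
        lat = raster@yll + (nr - rc[, 1] + 0.5) * raster@cellSize)
}

#' Raster value at point locations
#'
#' @param raster an [EnvRaster-class]
#' @param pts point `c(lon, lat)` or n x 2 matrix.
#' @return numeric vector; `NA` for masked cells or points outside the extent.
#' @export
rasterValueAt <- function(raster, pts) {
  rc <- .cellIndex(raster, pts)
  out <- rep(NA_real_, nrow(rc))
  ok <- !is.na(rc[, 1])
  out[ok] <- raster@values[cbind(rc[ok, 1], rc[ok, 2])]
  out
}
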