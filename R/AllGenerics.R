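#' @include AllClasses.R
NULL

#' @describeIn GeoTree-class number of tips
#' @param x a `GeoTree`
#' @export
setGeneric("nTips", function(x) standardGeneric("nTips"))

#' @export
setMethod("nTips", "GeoTree", function(x) {
  sum(!x@nodes$id %in% x@nodes$parent)
})

#' Node table of a GeoTree
#'
#' @param x a [GeoTree-class]
#' @return data.frame with one row per node (id, parent, time, lon, lat,
#'   label)
#' @export
setGeneric("nodeData", function(x) standardGeneric("nodeData"))

#' @export
setMethod("nodeData", "GeoTree", function(x) x@nodes)

#' Tip labels of a GeoTree
#' @param x a [GeoTree-class]
#' @export
setGeneric("tipLabels", function(x) standardGeneric("tipLabels"))

#' @export
setMethod("tipLabels", "GeoTree", function(x) {
  nd <- x@nodes
  nd$label[!nd$id %in% nd$parent]
})

#' Id and row of the root node
#' @param x a [GeoTree-class]
#' @export
setGeneric("rootNode", function(x) standardGeneric("rootNode"))

#' @export
setMethod("rootNode", "GeoTree", function(x) {
  x@nodes[is.na(x@nodes$parent), , drop = FALSE]
})

#' Per-branch data of an extraction table
#'
#' @param x an [ExtractionTable-class]
#' @return data.frame, one row per branch (movement vector)
#' @export
setGeneric("branchData", function(x) standardGeneric("branchData"))

#' @export
setMethod("branchData", "ExtractionTable", function(x) x@branches)

#' @export
setMethod("length", "HPDRegionSet", function(x) length(x@regions))

#' @export
setMethod("[[", "HPDRegionSet", function(x, i) x@regions[[i]])

#' Raster value matrix (row 1 = north)
#' @param x an [EnvRaster-class]
#' @export
setGeneric("rasterValues", function(x) standardGeneric("rasterValues"))

#' @export
setMethod("rasterValues", "EnvRaster", function(x) x@values)

#' Extent of a raster as c(xmin, xmax, ymin, ymax)
#' @param x an [EnvRaster-class]
#' @export
setGeneric("rasterExtent", function(x) standardGeneric("rasterExtent"))

#' @export
setMethod("rasterExtent", "EnvRaster", function(x) {
  c(xmin = x@xll, xmax = x@xll + ncol(x@values) * x@cellSize,
    ymin = x@yll, ymax = x@yll + nrow(x@values) * x@cellSize)
})

setMethod("show", "GeoTree", function(object) {
  nd <- object@nodes
  nt <- sum(!nd$id %in% nd$parent)
  cat(sprintf("GeoTree: %d tips, %d nodes%s\n", nt, nrow(nd),
              if (object@projected) " (projected)" else ""))
  cat(sprintf("  calendar span: %.4f .. %.4f\n", min(nd$time), max(nd$time)))
  if (length(object@annotations))
    cat(sprintf("  %d annotated nodes\n", length(object@annotations)))
})

setMethod("show", "ExtractionTable", function(object) {
  cat(sprintf("ExtractionTable: %d branches%s%s\n", nrow(object@branches),
              if (object@randomised) " (randomised)" else "",
              if (object@projected) " (projected)" else ""))
  if (nrow(object@branches)) {
    cat(sprintf("  time span: %.4f .. %.4f\n",
                min(object@branches$startTime), max(object@branches$endTime)))
    cat(sprintf("  total lineage length: %.2f km over %.2f yr\n",
                sum(object@branches$greatCircleDistance_km),
                sum(object@branches$duration)))
  }
})

setMethod("show", "EnvRaster", function(object) {
  e <- rasterExtent(object)
  cat(sprintf("EnvRaster '%s': %d x %d cells of %g, extent [%g, %g] x [%g, %g]\n",
              object@name, nrow(object@values), ncol(object@values),
              object@cellSize, e[1], e[2], e[3], e[4]))
  v <- object@values[is.finite(object@values)]
  cat(sprintf("  values: %g .. %g (%d missing cells)\n", min(v), max(v),
              sum(!is.finite(object@values))))
})

setMethod("show", "HPDRegion", function(object) {
  cat(sprintf("HPDRegion '%s': mass %.2f, %d ring(s)%s\n", object@label,
              object@mass, length(object@rings),
              if (object@flagged) " [degenerate]" else ""))
})

setMethod("show", "HPDRegionSet", function(object) {
  cat(sprintf("HPDRegionSet with %d region(s)\n", length(object@regions)))
  for (r in object@regions) show(r)
})

setMethod("show", "TestSupport", function(object) {
  cat(sprintf("TestSupport (%s): p = %.3f, BF = %.3g over %d trees%s\n",
              object@direction, object@p, object@bf, object@nTrees,
              if (object@degenerate) " [degenerate]" else ""))
})

setMethod("show", "QStatResult", function(object) {
  cat(sprintf("QStatResult: raster '%s', k = %g, model = %s\n",
              object@rasterName, object@k, object@model))
  cat(sprintf("  mean Q = %.4f, p = %.3f, BF = %.3g\n",
              mean(object@perTree$q), object@support@p, object@support@bf))
})

setMethod("show", "DispersalStatsSummary", function(object) {
  cat(sprintf("DispersalStatsSummary over %d posterior trees (mass %.2f)\n",
              nrow(object@perTree), object@mass))
  print(object@summaries, row.names = FALSE)
})
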