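#' @include AllClasses.R geo-utils.R
NULL

# internal constructor enforcing the duration clamp and column order
.newExtractionTable <- function(branches, treeIndex = NA_integer_,
                                mostRecentDate = NA_real_, projected = FALSE,
                                randomised = FALSE, flags = list()) {
  branches <- branches[, .BRANCH_COLUMNS, drop = FALSE]
  clamped <- which(branches$duration < .MIN_DURATION)
  if (length(clamped)) {
    branches$duration[clamped] <- .MIN_DURATION
    branches$endTime[clamped] <- branches$startTime[clamped] + .MIN_DURATION
    flags$clamped <- union(flags$clamped, clamped)
  }
  rownames(branches) <- NULL
  new("ExtractionTable", branches = branches,
      treeIndex = as.integer(treeIndex), mostRecentDate = mostRecentDate,
      projected = projected, randomised = randomised, flags = flags)
}

#' Decompose a tree into its branch movement vectors
#'
#' Every non-root node contributes one row describing the branch from its
#' parent: start/end calendar times, start/end locations, duration and the
#' great-circle distance covered (Euclidean km for projected trees). A
#' binary rooted tree with n tips yields 2n - 2 rows. Branches shorter than
#' 1e-8 yr are clamped to 1e-8 and flagged, keeping velocity and diffusion
#' ratios finite.
#'
#' @param tree a [GeoTree-class]
#' @return an [ExtractionTable-class]
#' @export
extractBranchTable <- function(tree) {
  nd <- tree@nodes
  if (anyDuplicated(nd$id)) stop("duplicate node ids")
  i <- which(!is.na(nd$parent))
  p <- match(nd$parent[i], nd$id)
  isTip <- !nd$id %in% nd$parent
  br <- data.frame(node1 = nd$id[p], node2 = nd$id[i],
                   startTime = nd$time[p], endTime = nd$time[i],
                   duration = nd$time[i] - nd$time[p],
                   startLon = nd$lon[p], startLat = nd$lat[p],
                   endLon = nd$lon[i], endLat = nd$lat[i],
                   greatCircleDistance_km = .pairDist(
                     cbind(nd$lon[p], nd$lat[p]), cbind(nd$lon[i], nd$lat[i]),
                     tree@projected),
                   tipFlag = isTip[i])
  .newExtractionTable(br, treeIndex = tree@treeIndex,
                      mostRecentDate = tree@mostRecentDate,
                      projected = tree@projected)
}

#' Write an extraction table as CSV
#'
#' Full-precision CSV with the canonical column set; a `# randomised=1`
#' metadata header line is prepended for randomised tables.
#'
#' @param table an [ExtractionTable-class]
#' @param path output path.
#' @export
writeExtractionTable <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (table@randomised) writeLines("# randomised=1", con)
  br <- table@branches
  num <- vapply(br, is.numeric, TRUE)
  br[num] <- lapply(br[num], function(x) sprintf("%.17g", x))
  utils::write.csv(br, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an extraction table from CSV
#'
#' @param path CSV path written by [writeExtractionTable()].
#' @param mostRecentDate,projected metadata not stored in the CSV.
#' @return an [ExtractionTable-class]
#' @export
readExtractionTable <- function(path, mostRecentDate = NA_real_,
                                projected = FALSE) {
  lines <- readLines(path)
  randomised <- length(lines) && grepl("^#\\s*randomised=1", lines[1])
  if (randomised) lines <- lines[-1]
  br <- utils::read.csv(text = paste(lines, collapse = "\n"),
                        stringsAsFactors = FALSE)
  if (!all(.BRANCH_COLUMNS %in% names(br)))
    stop("CSV is missing required columns: ",
         paste(setdiff(.BRANCH_COLUMNS, names(br)), collapse = ", "))
  numCols <- setdiff(.BRANCH_COLUMNS, "tipFlag")
  for (cn in numCols) {
    v <- suppressWarnings(as.numeric(br[[cn]]))
    bad <- which(is.na(v) & !is.na(br[[cn]]))
    if (length(bad))
      stop(sprintf("malformed value in column '%s' at data row %d", cn, bad[1]))
    br[[cn]] <- v
  }
  br$tipFlag <- as.logical(br$tipFlag)
  br$node1 <- as.integer(br$node1)
  br$node2 <- as.integer(br$node2)
  .newExtractionTable(br, mostRecentDate = mostRecentDate,
                      projected = projected, randomised = randomised)
}

#' Prune a tree to a subset of its tips
#'
#' Drops all other tips, removes the resulting unary (degree-2) pass-through
#' nodes, and merges their branches: the merged branch runs straight from
#' the retained ancestor to the retained descendant, so its displacement is
#' the net displacement of the unobserved path. This is exactly what a
#' sparser sampling of the same epidemic would have recorded, and is the
#' matched design used to study the sensitivity of dispersal statistics to
#' sampling intensity.
#'
#' @param tree a [GeoTree-class]
#' @param tips tip labels (or tip node ids) to keep; at least 2.
#' @return a [GeoTree-class]
#' @export
subsampleTips <- function(tree, tips) {
  nd <- tree@nodes
  isTip <- !nd$id %in% nd$parent
  keepIds <- if (is.character(tips)) nd$id[isTip][match(tips, nd$label[isTip])]
  else as.integer(tips)
  if (anyNA(keepIds) || !all(keepIds %in% nd$id[isTip]))
    stop("unknown tip in 'tips'")
  if (length(keepIds) < 2L) stop("keep at least 2 tips")
  .pruneNodeTable(tree, keepIds)
}

# shared pruning core (also used to drop extinct birth-death lineages)
.pruneNodeTable <- function(tree, keepIds) {
  nd <- .pruneDf(tree@nodes, keepIds)
  ann <- tree@annotations[names(tree@annotations) %in% as.character(nd$id)]
  new("GeoTree", nodes = nd, annotations = ann,
      mostRecentDate = tree@mostRecentDate, projected = tree@projected,
      treeIndex = tree@treeIndex)
}

# data.frame-level pruning: keep the given tips and their ancestors, then
# collapse unary pass-through nodes (branch durations merge through times)
.pruneDf <- function(nd, keepIds) {
  keep <- nd$id %in% keepIds
  # mark all ancestors of kept tips
  idx <- match(nd$id, nd$id)
  parentRow <- match(nd$parent, nd$id)
  for (i in which(keep)) {
    p <- parentRow[i]
    while (!is.na(p) && !keep[p]) { keep[p] <- TRUE; p <- parentRow[p] }
  }
  nd <- nd[keep, , drop = FALSE]
  # re-wire parents to the nearest kept ancestor (already guaranteed kept)
  nd$parent[!nd$parent %in% nd$id & !is.na(nd$parent)] <- NA  # safety
  # collapse unary nodes: repeat until every internal node has 2 children
  repeat {
    kids <- table(factor(nd$parent, levels = nd$id))
    unary <- nd$id[kids == 1L]
    unary <- setdiff(unary, keepIds)        # never collapse a kept tip
    if (!length(unary)) break
    u <- unary[1]
    child <- nd$id[!is.na(nd$parent) & nd$parent == u]
    nd$parent[nd$id == child] <- nd$parent[nd$id == u]
    nd <- nd[nd$id != u, , drop = FALSE]
  }
  # the root may have become unary as well
  repeat {
    rootId <- nd$id[is.na(nd$parent)]
    kids <- nd$id[!is.na(nd$parent) & nd$parent == rootId]
    if (length(kids) != 1L || rootId %in% keepIds) break
    nd <- nd[nd$id != rootId, , drop = FALSE]
    nd$parent[nd$id == kids] <- NA
  }
  nd
}

#' Patristic durations between tips
#'
#' Time separating each pair of tips along the tree: the sum of branch
#' durations on the path through their most recent common ancestor,
#' i.e. (t_i - t_mrca) + (t_j - t_mrca) in calendar time.
#'
#' @param tree a [GeoTree-class]
#' @return symmetric matrix (years), dimnames = tip labels.
#' @export
patristicDurations <- function(tree) {
  nd <- tree@nodes
  isTip <- !nd$id %in% nd$parent
  tipRows <- which(isTip)
  n <- length(tipRows)
  parentRow <- match(nd$parent, nd$id)
  anc <- lapply(tipRows, function(i) {
    path <- i
    while (!is.na(parentRow[path[length(path)]]))
      path <- c(path, parentRow[path[length(path)]])
    path
  })
  out <- matrix(0, n, n, dimnames = list(nd$label[tipRows], nd$label[tipRows]))
  for (a in seq_len(n - 1L)) for (b in seq.int(a + 1L, n)) {
    common <- intersect(anc[[a]], anc[[b]])
    tm <- max(nd$time[common])
    out[a, b] <- out[b, a] <- (nd$time[tipRows[a]] - tm) +
      (nd$time[tipRows[b]] - tm)
  }
  out
}
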