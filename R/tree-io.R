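#' @include AllClasses.R geo-utils.R
NULL

# ---------------------------------------------------------------------------
# BEAST-style annotated NEXUS: tree statements carry node comments of the
# form [&key=value,key={a,b},key={{..},{..}}]. No installed package keeps
# those comments, so the tokenizer/recursive-descent parser lives here.
# ---------------------------------------------------------------------------

#' Parse annotated posterior trees
#'
#' Reads a BEAST-style annotated NEXUS file holding a posterior sample of
#' time-scaled trees whose nodes are annotated with geographic coordinates,
#' applies a burn-in, and draws a seeded uniform subsample without
#' replacement. Node ages are converted to calendar times (decimal years)
#' anchored so that the most recent tip of each tree sits at
#' `mostRecentSamplingDate`.
#'
#' Coordinates may be stored either as a bivariate annotation
#' (`location={lat, lon}`, BEAST order: latitude first) or as a split pair
#' (`location1` = latitude, `location2` = longitude). A tree mixing both
#' conventions is rejected. The package's internal order is always
#' (lon, lat).
#'
#' @param stream path to a NEXUS file, or its lines as a character vector.
#' @param locationAnnotation annotation name carrying the coordinates
#'   (default `"location"`).
#' @param mostRecentSamplingDate calendar time (decimal year) of the most
#'   recent tip.
#' @param burnInFraction fraction of initial trees to discard, in [0, 1).
#' @param nToSample number of post-burn-in trees to draw (`NULL` = all).
#' @param seed integer seed for the subsample draw.
#' @return list of [GeoTree-class]
#' @export
parseAnnotatedTrees <- function(stream, locationAnnotation = "location",
                                mostRecentSamplingDate = 0,
                                burnInFraction = 0, nToSample = NULL,
                                seed = 1L) {
  if (burnInFraction < 0 || burnInFraction >= 1)
    stop("burnInFraction must lie in [0, 1)")
  lines <- if (length(stream) == 1L && !grepl("\n", stream) &&
               file.exists(stream)) readLines(stream) else
    unlist(strsplit(stream, "\n", fixed = TRUE))
  translate <- .parseTranslate(lines)
  treeLines <- grep("^\\s*tree\\s", lines, ignore.case = TRUE, value = TRUE)
  if (!length(treeLines)) stop("no tree statements found")
  total <- length(treeLines)
  keep <- seq.int(floor(burnInFraction * total) + 1L, total)
  if (is.null(nToSample)) nToSample <- length(keep)
  if (nToSample > length(keep))
    stop(sprintf("nToSample (%d) exceeds the %d post-burn-in trees",
                 nToSample, length(keep)))
  set.seed(seed)
  idx <- sort(sample(keep, nToSample))
  lapply(idx, function(i)
    .buildGeoTree(treeLines[i], translate, locationAnnotation,
                  mostRecentSamplingDate, treeIndex = i))
}

.parseTranslate <- function(lines) {
  start <- grep("^\\s*translate\\s*$", lines, ignore.case = TRUE)
  if (!length(start)) return(NULL)
  map <- character(0)
  for (i in seq.int(start[1] + 1L, length(lines))) {
    l <- trimws(lines[i])
    if (l == ";") break
    l <- sub(",$", "", sub(";$", "", l))
    done <- grepl(";\\s*$", lines[i])
    parts <- strsplit(l, "\\s+")[[1]]
    if (length(parts) >= 2L) map[parts[1]] <- gsub("^'|'$", "", parts[2])
    if (done) break
  }
  map
}

# parse one "tree NAME [...] = [&R] (...);" statement into a GeoTree
.buildGeoTree <- function(statement, translate, locationAnnotation,
                          mostRecentSamplingDate, treeIndex = NA_integer_) {
  nwk <- sub("^[^=]*=\\s*", "", statement)
  nwk <- gsub("^\\s*\\[[^]]*\\]\\s*", "", nwk)  # rooting comment [&R]
  nwk <- trimws(sub(";\\s*$", "", nwk))
  env <- new.env(parent = emptyenv())
  env$s <- nwk; env$pos <- 1L; env$n <- 0L
  env$parent <- integer(0); env$len <- numeric(0)
  env$label <- character(0); env$annot <- list()
  root <- .parseClade(env, NA_integer_)
  if (env$pos <= nchar(env$s))
    stop("trailing characters after newick string: ",
         substr(env$s, env$pos, env$pos + 20L))
  n <- env$n
  label <- env$label
  if (!is.null(translate)) {
    hit <- !is.na(label) & label %in% names(translate)
    label[hit] <- translate[label[hit]]
  }
  # raw node times: root at 0, increasing toward the tips
  rawTime <- numeric(n)
  ord <- order(.depths(env$parent))
  for (i in ord) if (!is.na(env$parent[i]))
    rawTime[i] <- rawTime[env$parent[i]] + env$len[i]
  isTip <- !(seq_len(n) %in% env$parent)
  shift <- mostRecentSamplingDate - max(rawTime[isTip])
  coords <- .extractCoords(env$annot, locationAnnotation, label, isTip)
  nodes <- data.frame(id = seq_len(n), parent = env$parent,
                      time = rawTime + shift,
                      lon = coords[, 1], lat = coords[, 2],
                      label = ifelse(isTip, label, NA_character_),
                      stringsAsFactors = FALSE)
  keepAnn <- env$annot[vapply(env$annot, length, 1L) > 0]
  names(keepAnn) <- as.character(which(vapply(env$annot, length, 1L) > 0))
  kids <- table(factor(env$parent, levels = seq_len(n)))
  if (any(!isTip & kids != 2L))
    stop("tree is not strictly binary (polytomy or unary node present)")
  new("GeoTree", nodes = nodes, annotations = keepAnn,
      mostRecentDate = mostRecentSamplingDate, projected = FALSE,
      treeIndex = as.integer(treeIndex))
}

.depths <- function(parent) {
  d <- integer(length(parent))
  for (i in seq_along(parent)) {
    p <- parent[i]; k <- 0L
    while (!is.na(p)) { k <- k + 1L; p <- parent[p] }
    d[i] <- k
  }
  d
}

.extractCoords <- function(annots, name, label, isTip) {
  n <- length(annots)
  out <- matrix(NA_real_, n, 2L)
  n1 <- paste0(name, "1"); n2 <- paste0(name, "2")
  sawJoint <- FALSE; sawSplit <- FALSE
  for (i in seq_len(n)) {
    a <- annots[[i]]
    who <- if (isTip[i] && !is.na(label[i])) sprintf("tip '%s'", label[i]) else
      sprintf("node %d", i)
    if (!is.null(a[[name]])) {
      sawJoint <- TRUE
      v <- a[[name]]
      if (!is.numeric(v) || length(v) != 2L)
        stop(sprintf("annotation '%s' on %s is not a coordinate pair",
                     name, who))
      out[i, ] <- c(v[2], v[1])  # stored (lat, lon) -> internal (lon, lat)
    } else if (!is.null(a[[n1]]) && !is.null(a[[n2]])) {
      sawSplit <- TRUE
      out[i, ] <- c(a[[n2]][1], a[[n1]][1])
    } else {
      stop(sprintf("missing location annotation '%s' on %s", name, who))
    }
  }
  if (sawJoint && sawSplit)
    stop("tree mixes joint and split location annotations")
  out
}

# --- newick tokenizer -------------------------------------------------------

.peek <- function(env) substr(env$s, env$pos, env$pos)

.parseClade <- function(env, parentId) {
  env$n <- env$n + 1L
  id <- env$n
  env$parent[id] <- parentId
  env$len[id] <- 0
  env$label[id] <- NA_character_
  env$annot[[id]] <- list()
  if (.peek(env) == "(") {
    env$pos <- env$pos + 1L
    repeat {
      .parseClade(env, id)
      ch <- .peek(env)
      if (ch == ",") { env$pos <- env$pos + 1L; next }
      if (ch == ")") { env$pos <- env$pos + 1L; break }
      stop("malformed newick near position ", env$pos)
    }
  }
  lbl <- .readToken(env)
  if (nzchar(lbl)) env$label[id] <- lbl
  while (.peek(env) == "[") .mergeComment(env, id)
  if (.peek(env) == ":") {
    env$pos <- env$pos + 1L
    while (.peek(env) == "[") .mergeComment(env, id)
    env$len[id] <- .readNumber(env)
  }
  id
}

.readToken <- function(env) {
  if (.peek(env) == "'") {  # quoted label
    close <- regexpr("'", substr(env$s, env$pos + 1L, nchar(env$s)),
                     fixed = TRUE)
    tok <- substr(env$s, env$pos + 1L, env$pos + close - 1L)
    env$pos <- env$pos + close + 1L
    return(tok)
  }
  m <- regexpr("^[^,():;\\[\\]]*", substr(env$s, env$pos, nchar(env$s)),
               perl = TRUE)
  tok <- regmatches(substr(env$s, env$pos, nchar(env$s)), m)
  env$pos <- env$pos + nchar(tok)
  tok
}

.readNumber <- function(env) {
  m <- regexpr("^[-+0-9.eE]+", substr(env$s, env$pos, nchar(env$s)))
  tok <- regmatches(substr(env$s, env$pos, nchar(env$s)), m)
  if (!nzchar(tok)) stop("expected branch length at position ", env$pos)
  env$pos <- env$pos + nchar(tok)
  as.numeric(tok)
}

.mergeComment <- function(env, id) {
  # env$pos is on '['; find the matching ']' (comments do not nest)
  rest <- substr(env$s, env$pos, nchar(env$s))
  close <- regexpr("]", rest, fixed = TRUE)
  if (close < 0) stop("unterminated comment at position ", env$pos)
  body <- substr(rest, 2L, close - 1L)
  env$pos <- env$pos + close
  if (startsWith(body, "&"))
    env$annot[[id]] <- c(env$annot[[id]],
                         .parseAnnotations(substr(body, 2L, nchar(body))))
  invisible(NULL)
}

# split "k1=v1,k2={a,b},k3={{..},{..}}" at top-level commas
.splitTop <- function(s, sep = ",") {
  depth <- 0L; out <- character(0); start <- 1L
  chars <- strsplit(s, "")[[1]]
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch %in% c("{", "(")) depth <- depth + 1L
    else if (ch %in% c("}", ")")) depth <- depth - 1L
    else if (ch == sep && depth == 0L) {
      out <- c(out, substr(s, start, i - 1L)); start <- i + 1L
    }
  }
  c(out, substr(s, start, nchar(s)))
}

.parseAnnotations <- function(body) {
  out <- list()
  for (item in .splitTop(body)) {
    eq <- regexpr("=", item, fixed = TRUE)
    if (eq < 0) next
    key <- substr(item, 1L, eq - 1L)
    out[[key]] <- .parseAnnotValue(substr(item, eq + 1L, nchar(item)))
  }
  out
}

.parseAnnotValue <- function(v) {
  if (startsWith(v, "{")) {
    inner <- substr(v, 2L, nchar(v) - 1L)
    parts <- .splitTop(inner)
    if (length(parts) && startsWith(trimws(parts[1]), "{"))
      return(lapply(parts, .parseAnnotValue))
    num <- suppressWarnings(as.numeric(parts))
    return(if (anyNA(num)) gsub('^"|"$', "", parts) else num)
  }
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) num else gsub('^"|"$', "", v)
}

# --- writing ---------------------------------------------------------------

.formatAnnotValue <- function(v) {
  if (is.list(v))
    return(paste0("{", paste(vapply(v, .formatAnnotValue, ""),
                             collapse = ","), "}"))
  if (is.numeric(v)) {
    s <- sprintf("%.12g", v)
    return(if (length(s) > 1L) paste0("{", paste(s, collapse = ","), "}") else s)
  }
  if (length(v) > 1L) paste0("{", paste(v, collapse = ","), "}") else
    as.character(v)
}

.nodeComment <- function(annot) {
  if (!length(annot)) return("")
  items <- vapply(names(annot), function(k)
    paste0(k, "=", .formatAnnotValue(annot[[k]])), "")
  paste0("[&", paste(items, collapse = ","), "]")
}

.newickString <- function(tree, withAnnotations = TRUE, translate = NULL) {
  nd <- tree@nodes
  childOf <- split(nd$id, factor(nd$parent, levels = nd$id))
  rootId <- nd$id[is.na(nd$parent)]
  ann <- function(id) {
    a <- tree@annotations[[as.character(id)]]
    if (is.null(a)) a <- list()
    if (withAnnotations) {
      i <- match(id, nd$id)
      a$location <- c(nd$lat[i], nd$lon[i])  # BEAST order: lat first
      .nodeComment(a)
    } else ""
  }
  build <- function(id) {
    i <- match(id, nd$id)
    kids <- childOf[[as.character(id)]]
    len <- if (is.na(nd$parent[i])) NULL else
      nd$time[i] - nd$time[match(nd$parent[i], nd$id)]
    lenStr <- if (is.null(len)) "" else sprintf(":%.12g", len)
    if (length(kids)) {
      paste0("(", paste(vapply(kids, build, ""), collapse = ","), ")",
             ann(id), lenStr)
    } else {
      lbl <- nd$label[i]
      if (!is.null(translate)) lbl <- names(translate)[match(lbl, translate)]
      paste0(lbl, ann(id), lenStr)
    }
  }
  paste0(build(rootId), ";")
}

#' Write trees as an annotated NEXUS file
#'
#' Writes a list of [GeoTree-class] objects in the BEAST dialect this package
#' parses: a taxa block, a translate table, and one annotated tree statement
#' per sample with `location={lat, lon}` node comments (plus any other
#' annotations the trees carry, e.g. HPD-contour vertex arrays).
#'
#' @param trees a [GeoTree-class] or list of them (shared tip label set).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAnnotatedNexus <- function(trees, path) {
  if (is(trees, "GeoTree")) trees <- list(trees)
  labs <- sort(tipLabels(trees[[1]]))
  translate <- stats::setNames(labs, as.character(seq_along(labs)))
  out <- c("#NEXUS", "Begin taxa;",
           sprintf("\tDimensions ntax=%d;", length(labs)),
           "\tTaxlabels", paste0("\t\t", labs), "\t\t;", "End;",
           "Begin trees;", "\tTranslate",
           paste0("\t\t", seq_along(labs), " ", labs,
                  c(rep(",", length(labs) - 1L), "")),
           "\t\t;")
  for (i in seq_along(trees))
    out <- c(out, sprintf("tree STATE_%d = [&R] %s", i - 1L,
                          .newickString(trees[[i]], translate = translate)))
  writeLines(c(out, "End;"), path)
  invisible(path)
}

#' Convert a GeoTree to an ape phylo object
#'
#' Branch lengths are durations in decimal years. Internal node order
#' follows ape's convention (tips first). Coordinates and annotations are
#' dropped; use this for interoperability with tree utilities.
#'
#' @param tree a [GeoTree-class]
#' @return an [ape::phylo] object
#' @export
asPhylo <- function(tree) {
  nd <- tree@nodes
  isTip <- !nd$id %in% nd$parent
  nTip <- sum(isTip)
  apeId <- integer(nrow(nd))
  apeId[isTip] <- seq_len(nTip)
  internal <- which(!isTip)
  internal <- c(internal[is.na(nd$parent[internal])],
                internal[!is.na(nd$parent[internal])])  # root first: nTip + 1
  apeId[internal] <- nTip + seq_along(internal)
  nonroot <- which(!is.na(nd$parent))
  edge <- cbind(apeId[match(nd$parent[nonroot], nd$id)], apeId[nonroot])
  lens <- nd$time[nonroot] - nd$time[match(nd$parent[nonroot], nd$id)]
  phy <- list(edge = edge, edge.length = lens,
              tip.label = nd$label[isTip], Nnode = sum(!isTip))
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}
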