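#' @include fixtures.R
NULL

#' Polygon annotation set
#'
#' Polygon regions with class labels plus a total priority order over
#' classes, "more specific first", used to resolve overlapping
#' annotations into a single class per pixel.
#'
#' @slot regions list of regions; each a list with \code{polygon} (an
#'   n x 2 matrix of 0-based (x, y) vertices, n >= 3) and \code{class}.
#' @slot priority character vector ordering classes from most to least
#'   specific; must cover every annotated class.
#' @exportClass AnnotationSet
setClass("AnnotationSet", representation(regions = "list", priority = "character"))

setValidity("AnnotationSet", function(object) {
  for (r in object@regions) {
    if (is.null(r$polygon) || is.null(r$class))
      return("each region needs 'polygon' and 'class'")
    if (!r$class %in% object@priority)
      return(sprintf("class '%s' missing from the priority order", r$class))
  }
  TRUE
})

#' Construct an AnnotationSet
#'
#' @param regions list of regions (see \linkS4class{AnnotationSet}).
#' @param priority class priority order, most specific first.
#' @return an \linkS4class{AnnotationSet}.
#' @export
AnnotationSet <- function(regions, priority = classPriority()) {
  new("AnnotationSet", regions = regions, priority = priority)
}

#' Resolve overlapping polygon annotations into a label map
#'
#' Annotation post-processing: every pixel covered by several polygons
#' receives the highest-priority (most specific) class among them — for
#' example a pixel annotated as both "body" and "eye" becomes "eye".
#' Uncovered pixels are background. The result is independent of the
#' order in which regions are listed, and re-applying the rule to its own
#' output changes nothing.
#'
#' @param annotations an \linkS4class{AnnotationSet}.
#' @param imageSize c(width, height) in pixels.
#' @param classes class list for the output map.
#' @return a \linkS4class{LabelMap}.
#' @export
resolveOverlaps <- function(annotations, imageSize,
                            classes = anatomyClasses()) {
  W <- imageSize[1]; H <- imageSize[2]
  priority <- annotations@priority
  bgRank <- match("background", priority)
  if (is.na(bgRank)) bgRank <- length(priority) + 1L
  rank <- matrix(bgRank, H, W)
  label <- matrix(0L, H, W)
  for (r in annotations@regions) {
    poly <- r$polygon
    if (nrow(poly) < 3L)
      stop("polygons need at least 3 vertices")
    clsIdx <- match(r$class, classes)
    if (is.na(clsIdx)) stop(sprintf("class '%s' not in the class list", r$class))
    pr <- match(r$class, priority)
    x0 <- max(0L, floor(min(poly[, 1]))); x1 <- min(W - 1L, ceiling(max(poly[, 1])))
    y0 <- max(0L, floor(min(poly[, 2]))); y1 <- min(H - 1L, ceiling(max(poly[, 2])))
    if (x1 < x0 || y1 < y0) next
    xs <- rep(x0:x1, each = y1 - y0 + 1L)
    ys <- rep(y0:y1, times = x1 - x0 + 1L)
    inside <- pointsInPolygon(xs, ys, poly[, 1], poly[, 2])
    if (!any(inside)) next
    sel <- cbind(ys[inside] + 1L, xs[inside] + 1L)
    better <- rank[sel] > pr
    if (any(better)) {
      sel <- sel[better, , drop = FALSE]
      rank[sel] <- pr
      label[sel] <- clsIdx - 1L
    }
  }
  LabelMap(label, classes)
}

#' Per-pixel class decision from a score raster
#'
#' Assigns each pixel the class with the highest score (the position of
#' the maximum among the N per-class values); exact ties go to the lowest
#' class index.
#'
#' @param prob a \linkS4class{ProbabilityMap}.
#' @return a \linkS4class{LabelMap}.
#' @export
argmaxClasses <- function(prob) {
  s <- scoreArray(prob)
  if (!all(is.finite(s))) stop("scores must be finite")
  d <- dim(s)
  m <- matrix(s, d[1] * d[2], d[3])
  idx <- max.col(m, ties.method = "first") - 1L
  LabelMap(matrix(idx, d[1], d[2]), classNames(prob))
}

# Tile start offsets along one axis: stride tileSize - overlap, with the
# final tile clamped flush to the far edge so coverage is exact.
tileOffsets <- function(size, tileSize, overlap) {
  if (size <= tileSize) return(0L)
  stride <- tileSize - overlap
  off <- seq.int(0L, size - tileSize, by = stride)
  if (off[length(off)] != size - tileSize) off <- c(off, size - tileSize)
  off
}

#' Cut an image into overlapping tiles
#'
#' Tiles are placed at stride \code{tileSize - overlap} along each axis,
#' with the final tile per axis clamped flush to the image edge. Images
#' smaller than a tile are reflect-padded up to tile size; the amount of
#' padding is recorded in the \code{pad} attribute of the result.
#'
#' @param image numeric matrix.
#' @param scheme a \linkS4class{TilingScheme}.
#' @return list of tiles, each a list with \code{tile} (matrix) and
#'   \code{offset} (0-based c(x, y) position in the padded image); the
#'   list carries attributes \code{pad} (c(x, y) padding added) and
#'   \code{paddedSize}.
#' @export
tileImage <- function(image, scheme = TilingScheme()) {
  ts <- scheme@tileSize
  padX <- max(0L, ts - ncol(image)); padY <- max(0L, ts - nrow(image))
  padded <- if (padX > 0L || padY > 0L)
    reflectPad(image, nrow(image) + padY, ncol(image) + padX) else image
  offX <- tileOffsets(ncol(padded), ts, scheme@overlap)
  offY <- tileOffsets(nrow(padded), ts, scheme@overlap)
  tiles <- list()
  for (oy in offY) for (ox in offX) {
    tiles[[length(tiles) + 1L]] <- list(
      tile = padded[oy + seq_len(ts), ox + seq_len(ts), drop = FALSE],
      offset = c(ox, oy))
  }
  attr(tiles, "pad") <- c(padX, padY)
  attr(tiles, "paddedSize") <- c(ncol(padded), nrow(padded))
  tiles
}

#' Stitch per-tile score rasters back into one map
#'
#' Each output pixel takes the scores of the covering tile whose center is
#' nearest to it. Segmentation networks are least reliable near the edge
#' of their input, so trusting the tile in which a pixel is most central
#' discards exactly the distrusted edge regions of overlapping tiles.
#'
#' @param tiles list of tiles, each a list with \code{prob} (a
#'   \linkS4class{ProbabilityMap} of tile size) and \code{offset}
#'   (0-based c(x, y)).
#' @param scheme the \linkS4class{TilingScheme} used to cut the tiles.
#' @param imageSize c(width, height) of the stitched output.
#' @return a \linkS4class{ProbabilityMap} of the full image.
#' @export
stitchSegmentations <- function(tiles, scheme, imageSize) {
  W <- imageSize[1]; H <- imageSize[2]
  classes <- classNames(tiles[[1]]$prob)
  N <- length(classes)
  best <- matrix(Inf, H, W)
  assign <- matrix(0L, H, W)
  for (i in seq_along(tiles)) {
    off <- tiles[[i]]$offset
    d <- dim(scoreArray(tiles[[i]]$prob))
    rows <- off[2] + seq_len(d[1]); cols <- off[1] + seq_len(d[2])
    rows <- rows[rows <= H]; cols <- cols[cols <= W]
    if (length(rows) == 0L || length(cols) == 0L) next
    cx <- off[1] + (d[2] - 1) / 2; cy <- off[2] + (d[1] - 1) / 2
    dx2 <- ((cols - 1) - cx)^2
    dy2 <- ((rows - 1) - cy)^2
    d2 <- outer(dy2, dx2, "+")
    sub <- best[rows, cols, drop = FALSE]
    win <- d2 < sub
    if (any(win)) {
      sub[win] <- d2[win]
      best[rows, cols] <- sub
      subA <- assign[rows, cols, drop = FALSE]
      subA[win] <- i
      assign[rows, cols] <- subA
    }
  }
  if (any(!is.finite(best)))
    stop("tiles do not cover the image")
  out <- array(0, dim = c(H, W, N))
  for (i in seq_along(tiles)) {
    off <- tiles[[i]]$offset
    s <- scoreArray(tiles[[i]]$prob)
    d <- dim(s)
    rows <- off[2] + seq_len(d[1]); cols <- off[1] + seq_len(d[2])
    keepR <- rows <= H; keepC <- cols <= W
    rows <- rows[keepR]; cols <- cols[keepC]
    if (length(rows) == 0L || length(cols) == 0L) next
    sel <- assign[rows, cols, drop = FALSE] == i
    if (!any(sel)) next
    for (k in seq_len(N)) {
      o <- out[rows, cols, k]
      p <- s[which(keepR), which(keepC), k]
      o[sel] <- p[sel]
      out[rows, cols, k] <- o
    }
  }
  ProbabilityMap(out, classes)
}

#' Run a segmenter over an image via tiling and stitching
#'
#' @param image numeric matrix.
#' @param segmenter function mapping an image to a
#'   \linkS4class{ProbabilityMap} of identical size (the pluggable
#'   network interface).
#' @param scheme a \linkS4class{TilingScheme}.
#' @return a \linkS4class{ProbabilityMap} of the input size.
#' @export
segmentTiled <- function(image, segmenter, scheme = TilingScheme()) {
  tiles <- tileImage(image, scheme)
  segTiles <- lapply(tiles, function(tl) {
    prob <- segmenter(tl$tile)
    d <- dim(scoreArray(prob))
    if (d[1] != nrow(tl$tile) || d[2] != ncol(tl$tile))
      stop("segmenter output size does not match its input")
    list(prob = prob, offset = tl$offset)
  })
  padded <- attr(tiles, "paddedSize")
  prob <- stitchSegmentations(segTiles, scheme, padded)
  pad <- attr(tiles, "pad")
  if (any(pad > 0L)) {
    s <- scoreArray(prob)
    prob <- ProbabilityMap(s[seq_len(nrow(image)), seq_len(ncol(image)), ,
                             drop = FALSE], classNames(prob))
  }
  prob
}

#' Six-transform consensus segmentation
#'
#' Segments the image under the six square symmetries (identity,
#' rotations by 90/180/270 degrees, horizontal and vertical reflection),
#' maps each result back, and takes a per-pixel majority vote over the
#' six class decisions. Vote ties are broken by the annotation priority
#' order (most specific class wins), then by lowest class index.
#' Non-square images are reflect-padded to a square for the rotations and
#' cropped back afterwards.
#'
#' @param segmenter function mapping an image to a
#'   \linkS4class{ProbabilityMap} of identical size.
#' @param image numeric matrix.
#' @param priority class priority order used for tie-breaking.
#' @return a \linkS4class{LabelMap}.
#' @export
ttaConsensus <- function(segmenter, image, priority = classPriority()) {
  side <- max(nrow(image), ncol(image))
  sq <- reflectPad(image, side, side)
  trs <- symmetryTransforms()
  votes <- NULL
  classes <- NULL
  for (tr in trs) {
    timg <- tr$fwd(sq)
    prob <- segmenter(timg)
    d <- dim(scoreArray(prob))
    if (d[1] != nrow(timg) || d[2] != ncol(timg))
      stop("segmenter output size does not match its input")
    if (is.null(classes)) {
      classes <- classNames(prob)
      votes <- array(0L, dim = c(side, side, length(classes)))
    }
    lab <- tr$inv(labelRaster(argmaxClasses(prob)))
    for (k in seq_along(classes))
      votes[, , k] <- votes[, , k] + (lab == k - 1L)
  }
  # majority vote; scanning classes in priority order makes the most
  # specific class win ties (strict > keeps the earlier winner)
  ordIdx <- match(priority, classes)
  ordIdx <- ordIdx[!is.na(ordIdx)]
  ordIdx <- c(ordIdx, setdiff(seq_along(classes), ordIdx))
  bestCount <- matrix(-1L, side, side)
  winner <- matrix(0L, side, side)
  for (k in ordIdx) {
    v <- votes[, , k]
    better <- v > bestCount
    if (any(better)) {
      bestCount[better] <- v[better]
      winner[better] <- k - 1L
    }
  }
  LabelMap(winner[seq_len(nrow(image)), seq_len(ncol(image)), drop = FALSE],
           classes)
}

#' Full segmentation pipeline for one image
#'
#' Tiling + stitching, optionally wrapped in six-transform consensus
#' voting, followed by the per-pixel class decision.
#'
#' @param image numeric matrix.
#' @param segmenter function mapping an image to a
#'   \linkS4class{ProbabilityMap}.
#' @param scheme a \linkS4class{TilingScheme}.
#' @param tta logical; apply six-transform consensus.
#' @param priority class priority order for consensus tie-breaks.
#' @return a \linkS4class{LabelMap}.
#' @export
segmentImage <- function(image, segmenter, scheme = TilingScheme(),
                         tta = FALSE, priority = classPriority()) {
  if (tta) {
    ttaConsensus(function(img) segmentTiled(img, segmenter, scheme), image,
                 priority)
  } else {
    argmaxClasses(segmentTiled(image, segmenter, scheme))
  }
}

#' Largest connected component of one class
#'
#' A trained network can produce several disjoint areas for a class; the
#' pipeline keeps the area with the most pixels (8-connectivity).
#'
#' @param labels a \linkS4class{LabelMap}.
#' @param targetClass class name.
#' @return list with \code{mask} (logical matrix) and \code{absent}
#'   (TRUE when the class does not occur; the mask is then all-FALSE).
#' @export
largestComponent <- function(labels, targetClass) {
  idx <- match(targetClass, classNames(labels))
  if (is.na(idx)) stop(sprintf("class '%s' not in the class list", targetClass))
  mask <- labelRaster(labels) == idx - 1L
  if (!any(mask))
    return(list(mask = mask, absent = TRUE))
  comp <- labelComponents(mask)
  sizes <- tabulate(comp[comp > 0L])
  list(mask = comp == which.max(sizes), absent = FALSE)
}

#' Seeded training augmentation of an image/label pair
#'
#' Applies the same seeded geometric perturbation (right-angle rotation,
#' reflection, integer shift) to image and labels, plus a photometric
#' brightness offset to the image only. Used to enlarge training sets
#' for the pluggable network.
#'
#' @param image numeric matrix.
#' @param labels matching \linkS4class{LabelMap}.
#' @param seed integer seed.
#' @param maxShiftPx maximum absolute shift per axis.
#' @param maxBrightness maximum absolute brightness offset.
#' @return list with perturbed \code{image} and \code{labels}.
#' @export
augmentPair <- function(image, labels, seed = 1L, maxShiftPx = 10L,
                        maxBrightness = 0.1) {
  lab <- labelRaster(labels)
  if (!identical(dim(image), dim(lab)))
    stop("image and labels must have identical dimensions")
  withSeed(seed, {
    k <- sample(0:3, 1)
    doFlip <- sample(c(TRUE, FALSE), 1)
    dx <- sample(-maxShiftPx:maxShiftPx, 1)
    dy <- sample(-maxShiftPx:maxShiftPx, 1)
    bright <- runif(1, -maxBrightness, maxBrightness)
    geom <- function(m, fill) {
      m <- rotateRaster(m, k)
      if (doFlip) m <- flipHorizontal(m)
      out <- matrix(fill, nrow(m), ncol(m))
      srcR <- seq_len(nrow(m)) - dy
      srcC <- seq_len(ncol(m)) - dx
      okR <- srcR >= 1 & srcR <= nrow(m)
      okC <- srcC >= 1 & srcC <= ncol(m)
      out[which(okR), which(okC)] <- m[srcR[okR], srcC[okC]]
      out
    }
    list(image = clampValues(geom(image, stats::median(image)) + bright),
         labels = LabelMap(geom(lab, 0L), classNames(labels)))
  })
}

#' Deterministic pixel-wise reference segmenter for synthetic renders
#'
#' The synthetic renderer paints every anatomy class at its own gray
#' level, so classifying each pixel to the nearest paint level recovers
#' the ground truth on clean renders. Being strictly pixel-wise, this
#' reference segmenter is exactly translation-consistent, which makes it
#' the natural oracle for tiling/stitching and consensus machinery.
#'
#' @param levels named paint levels (defaults to [paintLevels()]).
#' @param classes class list; must match the names of \code{levels}.
#' @return function mapping an image to a \linkS4class{ProbabilityMap}
#'   (scores are negated distances to each class level).
#' @export
templateSegmenter <- function(levels = paintLevels(),
                              classes = anatomyClasses()) {
  lv <- levels[classes]
  function(image) {
    d <- c(dim(image), length(lv))
    s <- array(0, dim = d)
    for (k in seq_along(lv)) s[, , k] <- -abs(image - lv[k])
    ProbabilityMap(s, classes)
  }
}
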