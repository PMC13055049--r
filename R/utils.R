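#' @include AllGenerics.R
NULL

#' Anatomy class list and priority order
#'
#' `anatomyClasses()` returns the ordered class list used throughout the
#' pipeline; index 0 ("background") is implied for unannotated pixels.
#' `classPriority()` returns class names ordered from most to least
#' specific; when annotations or consensus votes overlap, the most
#' specific class wins (e.g. a pixel inside both "body" and "eye" is
#' labelled "eye").
#'
#' @return character vector of class names.
#' @export
anatomyClasses <- function() {
  c("background", "body", "eye", "yolk", "swim_bladder",
    "perivitelline_space", "duct_of_cuvier", "hindbrain")
}

#' @rdname anatomyClasses
#' @export
classPriority <- function() {
  c("eye", "swim_bladder", "yolk", "duct_of_cuvier",
    "perivitelline_space", "hindbrain", "body", "background")
}

#' Normalize an angle to [0, 360) degrees
#'
#' @param angleDeg angle in degrees (any real value).
#' @return equivalent angle in [0, 360).
#' @export
normalizeAngle <- function(angleDeg) {
  a <- angleDeg %% 360
  ifelse(a < 0, a + 360, a)
}

clampValues <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# Flatten macro steps, expanding repeat blocks. Used by validity and the
# macro executor; exported for introspection.
#' Flatten an injection macro's steps, expanding repeat blocks
#'
#' @param steps list of macro steps (possibly containing \code{repeat}
#'   steps with nested sub-steps).
#' @return flat list of primitive steps in execution order.
#' @export
flattenMacroSteps <- function(steps) {
  out <- list()
  for (s in steps) {
    if (identical(s$action, "repeat")) {
      inner <- flattenMacroSteps(s$steps)
      for (i in seq_len(s$k)) out <- c(out, inner)
    } else {
      out <- c(out, list(s))
    }
  }
  out
}

# Arithmetic centroid (pixel centers at integer 0-based coordinates) of a
# logical mask; returns c(x, y).
maskCentroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("cannot take the centroid of an empty mask")
  c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)
}

# 8-connected component labelling of a logical mask. Pixel adjacency is
# delegated to igraph's component search over the neighbour graph.
#' Label 8-connected components of a binary mask
#'
#' @param mask logical matrix.
#' @return integer matrix of the same shape; 0 for background, components
#'   numbered from 1 in no particular order.
#' @export
labelComponents <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  nr <- nrow(mask)
  id <- integer(length(mask)); id[idx] <- seq_along(idx)
  edges <- integer(0)
  # half of the 8-neighbourhood; the other half is implied by symmetry
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r <- ((idx - 1L) %% nr) + 1L
    co <- ((idx - 1L) %/% nr) + 1L
    r2 <- r + d[1]; c2 <- co + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(mask)
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- mask[nb]
    if (any(hit)) {
      from <- id[idx[ok][hit]]
      to <- id[nb[hit]]
      edges <- c(edges, rbind(from, to))
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

# Even-odd (crossing number) point-in-polygon test, vectorized over points.
# px, py: 0-based point coordinates; vx, vy: polygon vertices.
pointsInPolygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Square-symmetry transforms on matrices. rotateRaster(m, k) rotates by
# k * 90 degrees counter-clockwise in the y-down convention.
rotateRaster <- function(m, k) {
  k <- k %% 4L
  if (k == 0L) return(m)
  for (i in seq_len(k)) m <- t(m)[ncol(m):1, , drop = FALSE]
  m
}

flipHorizontal <- function(m) m[, ncol(m):1, drop = FALSE]
flipVertical <- function(m) m[nrow(m):1, , drop = FALSE]

# The six symmetry transforms used for consensus voting: identity, the
# three non-trivial rotations by multiples of 90 degrees, and the two
# axis-aligned reflections. Each entry carries the forward transform and
# its inverse.
symmetryTransforms <- function() {
  list(
    identity = list(fwd = function(m) m, inv = function(m) m),
    rot90    = list(fwd = function(m) rotateRaster(m, 1L),
                    inv = function(m) rotateRaster(m, 3L)),
    rot180   = list(fwd = function(m) rotateRaster(m, 2L),
                    inv = function(m) rotateRaster(m, 2L)),
    rot270   = list(fwd = function(m) rotateRaster(m, 3L),
                    inv = function(m) rotateRaster(m, 1L)),
    fliph    = list(fwd = flipHorizontal, inv = flipHorizontal),
    flipv    = list(fwd = flipVertical, inv = flipVertical)
  )
}

# Reflect-pad a matrix on the bottom/right to the requested size.
reflectPad <- function(m, targetRows, targetCols) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr >= targetRows && nc >= targetCols) return(m)
  rIdx <- seq_len(targetRows); cIdx <- seq_len(targetCols)
  reflect <- function(i, n) {
    # indices 1..n, n-1..1, 2..n, ... (mirror without repeating the edge)
    period <- max(2L * n - 2L, 1L)
    j <- (i - 1L) %% period
    ifelse(j < n, j + 1L, 2L * n - 1L - j)
  }
  m[reflect(rIdx, nr), reflect(cIdx, nc), drop = FALSE]
}

# Bilinear sampling of matrix m at 0-based continuous coordinates
# (xs, ys); out-of-range samples are clamped to the border.
bilinearSample <- function(m, xs, ys) {
  nr <- nrow(m); nc <- ncol(m)
  xs <- clampValues(xs, 0, nc - 1)
  ys <- clampValues(ys, 0, nr - 1)
  x0 <- floor(xs); y0 <- floor(ys)
  x1 <- pmin(x0 + 1, nc - 1); y1 <- pmin(y0 + 1, nr - 1)
  fx <- xs - x0; fy <- ys - y0
  at <- function(yy, xx) m[cbind(yy + 1, xx + 1)]
  v00 <- at(y0, x0); v01 <- at(y0, x1)
  v10 <- at(y1, x0); v11 <- at(y1, x1)
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

# deterministic RNG scope: evaluates expr with a local seed without
# touching the caller's RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
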