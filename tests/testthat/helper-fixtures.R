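# Shared helpers for building small in-code fixtures.

# A one-hot probability map from an integer label matrix.
oneHotProb <- function(raster, classes = anatomyClasses()) {
  s <- array(0, dim = c(nrow(raster), ncol(raster), length(classes)))
  for (k in seq_along(classes)) s[, , k] <- (raster == k - 1L) * 1
  ProbabilityMap(s, classes)
}

# A segmenter that ignores the image and returns a fixed probability map
# (used to drive stitching with known per-tile predictions).
constantSegmenter <- function(classIndex, classes = anatomyClasses()) {
  function(image) {
    s <- array(0, dim = c(dim(image), length(classes)))
    s[, , classIndex + 1L] <- 1
    ProbabilityMap(s, classes)
  }
}

# Brute-force per-pixel nearest-tile-center assignment (independent
# oracle for the stitching rule).
bruteStitchAssign <- function(tiles, imageSize) {
  W <- imageSize[1]; H <- imageSize[2]
  assign <- matrix(NA_integer_, H, W)
  for (y in 0:(H - 1)) for (x in 0:(W - 1)) {
    bestD <- Inf; bestI <- NA_integer_
    for (i in seq_along(tiles)) {
      off <- tiles[[i]]$offset
      d <- dim(scoreArray(tiles[[i]]$prob))
      if (x >= off[1] && x < off[1] + d[2] && y >= off[2] && y < off[2] + d[1]) {
        cx <- off[1] + (d[2] - 1) / 2; cy <- off[2] + (d[1] - 1) / 2
        dd <- (x - cx)^2 + (y - cy)^2
        if (dd < bestD) { bestD <- dd; bestI <- i }
      }
    }
    assign[y + 1, x + 1] <- bestI
  }
  assign
}

# A random simple (convex) polygon around a center: points on a circle.
randomPolygon <- function(cx, cy, rMin, rMax, nV = 6L) {
  th <- sort(runif(nV, 0, 2 * pi))
  r <- runif(nV, rMin, rMax)
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# Independent brute-force per-pixel priority scan over polygon regions.
brutePriorityScan <- function(regions, priority, imageSize,
                              classes = anatomyClasses()) {
  W <- imageSize[1]; H <- imageSize[2]
  out <- matrix(0L, H, W)
  for (y in 0:(H - 1)) for (x in 0:(W - 1)) {
    bestRank <- Inf; bestCls <- 0L
    for (r in regions) {
      vx <- r$polygon[, 1]; vy <- r$polygon[, 2]
      # crossing-number test for a single point
      inside <- FALSE
      j <- length(vx)
      for (i in seq_along(vx)) {
        if ((vy[i] > y) != (vy[j] > y) &&
            x < (vx[j] - vx[i]) * (y - vy[i]) / (vy[j] - vy[i]) + vx[i])
          inside <- !inside
        j <- i
      }
      if (inside) {
        rank <- match(r$class, priority)
        if (rank < bestRank) {
          bestRank <- rank
          bestCls <- match(r$class, classes) - 1L
        }
      }
    }
    out[y + 1, x + 1] <- bestCls
  }
  out
}

# Rigid rotation of a point about a center, angle in degrees (y-down CCW
# convention as used throughout the package).
rotatePoint <- function(p, center, angleDeg) {
  th <- angleDeg * pi / 180
  d <- p - center
  center + c(cos(th) * d[1] - sin(th) * d[2],
             sin(th) * d[1] + cos(th) * d[2])
}
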