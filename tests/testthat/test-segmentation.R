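# Segmentation machinery: overlap resolution, argmax, tiling, stitching,
# consensus voting, components, augmentation.

test_that("overlap resolution picks the most specific class per pixel", {
  # a body polygon containing an eye polygon: the shared pixels become eye
  body <- list(polygon = cbind(c(2, 28, 28, 2), c(2, 2, 28, 28)),
               class = "body")
  eye <- list(polygon = cbind(c(10, 18, 18, 10), c(10, 10, 18, 18)),
              class = "eye")
  lab <- resolveOverlaps(AnnotationSet(list(body, eye)), c(32, 32))
  r <- labelRaster(lab)
  eyeIdx <- match("eye", anatomyClasses()) - 1L
  bodyIdx <- match("body", anatomyClasses()) - 1L
  expect_identical(r[15, 15], eyeIdx)
  expect_identical(r[5, 5], bodyIdx)
  expect_identical(r[31, 31], 0L)   # uncovered pixel -> background
  # order independence
  lab2 <- resolveOverlaps(AnnotationSet(list(eye, body)), c(32, 32))
  expect_identical(labelRaster(lab2), r)
})

test_that("overlap resolution matches a brute-force per-pixel priority scan", {
  set.seed(42)
  classes <- anatomyClasses()
  usable <- setdiff(classPriority(), "background")
  for (case in 1:8) {
    nR <- sample(3:5, 1)
    regions <- lapply(seq_len(nR), function(i) {
      list(polygon = randomPolygon(runif(1, 8, 24), runif(1, 8, 24), 4, 10),
           class = sample(usable, 1))
    })
    ours <- labelRaster(resolveOverlaps(AnnotationSet(regions), c(32, 32)))
    brute <- brutePriorityScan(regions, classPriority(), c(32, 32))
    expect_identical(ours, brute)
  }
})

test_that("degenerate polygons are rejected", {
  bad <- list(polygon = cbind(c(1, 5), c(1, 5)), class = "eye")
  expect_error(resolveOverlaps(AnnotationSet(list(bad)), c(16, 16)),
               "3 vertices")
})

test_that("argmax class decision follows the stated tie rule", {
  s <- array(0, dim = c(1, 2, 3))
  s[1, 1, ] <- c(0.2, 0.5, 0.3)   # clear winner: class 1
  s[1, 2, ] <- c(0.5, 0.5, 0.1)   # tie -> lowest class index 0
  lab <- argmaxClasses(ProbabilityMap(s, c("a", "b", "c")))
  expect_identical(labelRaster(lab)[1, ], c(1L, 0L))
  # one-hot rasters round-trip exactly
  p <- generatePlate(2, c(360, 360), seed = 5, noiseSd = 0)
  prob <- oneHotProb(labelRaster(plateTruth(p)))
  expect_identical(labelRaster(argmaxClasses(prob)),
                   labelRaster(plateTruth(p)))
})

test_that("tiling follows the stride-and-clamp layout", {
  offs <- function(tiles, axis) sort(unique(vapply(tiles, function(t)
    t$offset[axis], numeric(1))))
  t1 <- tileImage(matrix(0, 304, 304))
  expect_length(t1, 1L)
  expect_identical(t1[[1]]$offset, c(0L, 0L))
  t2 <- tileImage(matrix(0, 304, 812))
  expect_identical(offs(t2, 1), c(0, 254, 508))
  t3 <- tileImage(matrix(0, 400, 400))
  expect_identical(offs(t3, 1), c(0, 96))
  expect_identical(offs(t3, 2), c(0, 96))
  # small images are reflect-padded, recorded in the pad attribute
  t4 <- tileImage(matrix(0, 100, 100))
  expect_identical(attr(t4, "pad"), c(204L, 204L))
  # every pairwise x-overlap of neighbouring tiles is at least the overlap
  expect_true(all(diff(offs(t2, 1)) <= 304 - 50))
})

test_that("stitching assigns each pixel to the nearest covering tile center", {
  # single tile: identity
  prob <- oneHotProb(matrix(2L, 32, 32))
  single <- stitchSegmentations(list(list(prob = prob, offset = c(0L, 0L))),
                                TilingScheme(32L, 8L), c(32, 32))
  expect_equal(scoreArray(single), scoreArray(prob))
  # two conflicting constant tiles: boundary at the midline between centers
  pA <- oneHotProb(matrix(1L, 20, 20)); pB <- oneHotProb(matrix(3L, 20, 20))
  tiles <- list(list(prob = pA, offset = c(0L, 0L)),
                list(prob = pB, offset = c(12L, 0L)))
  res <- stitchSegmentations(tiles, TilingScheme(20L, 8L), c(32, 20))
  lab <- labelRaster(argmaxClasses(res))
  assign <- bruteStitchAssign(tiles, c(32, 20))
  expect_identical(lab, matrix(c(1L, 3L)[assign], 20, 32))
  # uncovered pixels raise
  expect_error(stitchSegmentations(tiles, TilingScheme(20L, 8L), c(64, 20)),
               "cover")
})

test_that("tile-segment-stitch equals whole-image segmentation for a pixel-wise segmenter", {
  seg <- templateSegmenter()
  p <- generatePlate(3, c(420, 380), seed = 13)
  img <- plateImage(p)
  whole <- argmaxClasses(seg(img))
  tiled <- segmentImage(img, seg)
  expect_identical(labelRaster(tiled), labelRaster(whole))
})

test_that("consensus voting matches an exhaustive per-pixel vote, including ties", {
  classes <- anatomyClasses()
  priority <- classPriority()
  set.seed(7)
  for (case in 1:10) {
    base <- matrix(runif(32 * 32), 32, 32)
    # fixed random label rasters, one per symmetry transform
    perTransform <- lapply(1:6, function(i)
      matrix(sample(0:7, 32 * 32, replace = TRUE), 32, 32))
    trNames <- c("identity", "rot90", "rot180", "rot270", "fliph", "flipv")
    trs <- list(
      identity = function(m) m,
      rot90 = function(m) { for (i in 1:1) m <- t(m)[ncol(m):1, ]; m },
      rot180 = function(m) { for (i in 1:2) m <- t(m)[ncol(m):1, ]; m },
      rot270 = function(m) { for (i in 1:3) m <- t(m)[ncol(m):1, ]; m },
      fliph = function(m) m[, ncol(m):1],
      flipv = function(m) m[nrow(m):1, ])
    # the segmenter recognizes which transform it received and answers
    # with the transformed fixed labels, so inverse transport recovers
    # perTransform[[i]] exactly
    seg <- function(image) {
      for (i in seq_along(trNames)) {
        if (isTRUE(all.equal(image, trs[[i]](base))))
          return(oneHotProb(trs[[i]](perTransform[[i]]), classes))
      }
      stop("unexpected input image")
    }
    cons <- labelRaster(ttaConsensus(seg, base, priority))
    # independent exhaustive vote
    brute <- matrix(0L, 32, 32)
    for (y in 1:32) for (x in 1:32) {
      v <- vapply(perTransform, function(m) m[y, x], integer(1))
      counts <- table(factor(classes[v + 1], levels = classes))
      top <- names(counts)[counts == max(counts)]
      win <- top[which.min(match(top, priority))]
      brute[y, x] <- match(win, classes) - 1L
    }
    expect_identical(cons, brute)
  }
})

test_that("an equivariant segmenter makes consensus equal plain segmentation", {
  seg <- templateSegmenter()   # pixel-wise, hence equivariant
  p <- generatePlate(1, c(256, 256), seed = 2, noiseSd = 0)
  img <- plateImage(p)
  plain <- argmaxClasses(seg(img))
  cons <- ttaConsensus(seg, img)
  expect_identical(labelRaster(cons), labelRaster(plain))
  # consensus never invents classes absent from all votes
  expect_true(all(unique(as.vector(labelRaster(cons))) %in%
                    unique(as.vector(labelRaster(plain)))))
})

test_that("largest component selection matches brute force and flags absence", {
  m <- matrix(0L, 20, 20)
  m[2:4, 2:4] <- 2L          # 9-pixel eye component
  m[10:14, 10:14] <- 2L      # 25-pixel eye component
  lab <- LabelMap(m)
  res <- largestComponent(lab, "eye")
  expect_false(res$absent)
  expect_identical(sum(res$mask), 25L)
  expect_true(all(which(res$mask, arr.ind = TRUE) >= 10))
  single <- largestComponent(LabelMap(matrix(c(0L, 2L), 2, 2)), "eye")
  expect_identical(sum(single$mask), 2L)
  absent <- largestComponent(lab, "yolk")
  expect_true(absent$absent)
  expect_identical(sum(absent$mask), 0L)
  # diagonal touching counts as connected (8-connectivity)
  d <- matrix(0L, 4, 4); d[1, 1] <- 2L; d[2, 2] <- 2L
  expect_identical(sum(largestComponent(LabelMap(d), "eye")$mask), 2L)
})

test_that("augmentation transforms image and labels consistently", {
  p <- generatePlate(1, c(256, 256), seed = 6, noiseSd = 0)
  img <- plateImage(p); lab <- plateTruth(p)
  a1 <- augmentPair(img, lab, seed = 31, maxShiftPx = 0)
  a2 <- augmentPair(img, lab, seed = 31, maxShiftPx = 0)
  expect_identical(a1$image, a2$image)
  expect_identical(labelRaster(a1$labels), labelRaster(a2$labels))
  # with pure rotation/flip the class histogram is preserved
  expect_identical(table(labelRaster(a1$labels)), table(labelRaster(lab)))
  # non-background pixels overlap after identical geometric transforms
  expect_identical(dim(a1$image), dim(labelRaster(a1$labels)))
})
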