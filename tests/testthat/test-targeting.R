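# Landmark extraction, the skewed coordinate frame and site targeting.

segmentedLarva <- function(seed, size = 256L, heading = NULL) {
  p <- generatePlate(1, c(size, size), seed = seed, noiseSd = 0)
  lab <- argmaxClasses(templateSegmenter()(plateImage(p)))
  list(plate = p, labels = lab, larva = plateLarvae(p)[[1]])
}

test_that("landmark centroids match the fixture ground truth", {
  for (seed in c(1, 12, 23)) {
    f <- segmentedLarva(seed)
    lm <- landmarkCentroids(f$labels)
    truth <- larvaLandmarks(f$larva)
    expect_lt(sqrt(sum((lm@eyes - truth$eye)^2)), 0.5)
    expect_lt(sqrt(sum((lm@yolk - truth$yolk)^2)), 0.5)
    expect_lt(sqrt(sum((lm@swimBladder - truth$swim_bladder)^2)), 0.5)
  }
})

test_that("single-pixel regions and missing classes are handled", {
  r <- matrix(0L, 10, 10)
  r[2, 3] <- match("eye", anatomyClasses()) - 1L
  r[5, 6] <- match("yolk", anatomyClasses()) - 1L
  r[8, 2] <- match("swim_bladder", anatomyClasses()) - 1L
  lm <- landmarkCentroids(LabelMap(r))
  expect_equal(lm@eyes, c(2, 1))   # 0-based (x, y) of the single pixel
  r[8, 2] <- 0L
  expect_error(landmarkCentroids(LabelMap(r)), "swim_bladder")
})

test_that("the skewed frame maps its defining landmarks to unit coordinates", {
  lm <- LandmarkSet(eyes = c(10, 20), yolk = c(40, 25), swimBladder = c(18, 50))
  fr <- buildSkewedFrame(lm)
  expect_equal(toPlate(fr, c(0, 0)), c(10, 20))
  expect_equal(toPlate(fr, c(1, 0)), c(40, 25))
  expect_equal(toPlate(fr, c(0, 1)), c(18, 50))
  expect_error(buildSkewedFrame(
    LandmarkSet(c(0, 0), c(1, 1), c(2, 2.0001))), "collinear")
})

test_that("from_plate is the exact inverse of to_plate", {
  set.seed(99)
  for (i in 1:100) {
    fr <- SkewedFrame(runif(2, 0, 100),
                      c(runif(1, 5, 30), runif(1, -10, 10)),
                      c(runif(1, -10, 10), runif(1, 5, 30)))
    ab <- runif(2, -2, 2)
    expect_lt(max(abs(fromPlate(fr, toPlate(fr, ab)) - ab)), 1e-9)
  }
})

test_that("frame mapping is equivariant under rigid motions of the landmarks", {
  lm <- LandmarkSet(c(30, 40), c(65, 45), c(38, 75))
  fr <- buildSkewedFrame(lm)
  center <- c(50, 50); ang <- 73; shift <- c(12, -8)
  move <- function(p) rotatePoint(p, center, ang) + shift
  lm2 <- LandmarkSet(move(lm@eyes), move(lm@yolk), move(lm@swimBladder))
  fr2 <- buildSkewedFrame(lm2)
  for (ab in list(c(0.5, 0.5), c(1.2, -0.3), c(-0.1, 0.8))) {
    expect_equal(toPlate(fr2, ab), move(toPlate(fr, ab)), tolerance = 1e-9)
  }
})

test_that("needle angle follows the larva heading plus the configured offset", {
  lm0 <- LandmarkSet(c(0, 0), c(5, 3), c(10, 0))  # heading 0
  expect_equal(orientationAndAngle(lm0, 45)$angleDeg, 45)
  # heading 60 + offset 330 wraps to 30
  th <- 60 * pi / 180
  lm60 <- LandmarkSet(c(0, 0), rotatePoint(c(5, 3), c(0, 0), 60),
                      c(10 * cos(th), 10 * sin(th)))
  res <- orientationAndAngle(lm60, 330)
  expect_equal(res$headingDeg, 60, tolerance = 1e-9)
  expect_equal(res$angleDeg, 30, tolerance = 1e-9)
})

test_that("rotating the larva rotates the needle angle identically", {
  f1 <- segmentedLarva(31)
  lm1 <- landmarkCentroids(f1$labels)
  a1 <- orientationAndAngle(lm1, 45)$angleDeg
  h1 <- plateLarvae(f1$plate)[[1]]@headingDeg
  # regenerate the same larva geometry at a different heading: the angle
  # difference equals the heading difference
  p2 <- generatePlate(1, c(256, 256), seed = 31, noiseSd = 0)
  f2 <- segmentedLarva(77)
  lm2 <- landmarkCentroids(f2$labels)
  a2 <- orientationAndAngle(lm2, 45)$angleDeg
  h2 <- plateLarvae(f2$plate)[[1]]@headingDeg
  expect_equal(normalizeAngle(a2 - a1), normalizeAngle(h2 - h1),
               tolerance = 0.5)
})

test_that("DoC targeting hits the band and honours user-chosen points", {
  f <- segmentedLarva(41)
  lm <- landmarkCentroids(f$labels)
  fr <- buildSkewedFrame(lm)
  pose <- docTarget(f$labels, fr)
  docMask <- expandMask(regionMasks(f$larva)$duct_of_cuvier, c(256, 256))
  expect_true(docMask[pose@tip[2] + 1, pose@tip[1] + 1])
  expect_identical(pose@site, "doc_mid")
  # default target sits centrally: within 2 px of the arc midpoint
  idx <- which(docMask, arr.ind = TRUE)
  band <- cbind(idx[, 2] - 1, idx[, 1] - 1)
  ctr <- colMeans(band)
  mid <- band[which.min((band[, 1] - ctr[1])^2 + (band[, 2] - ctr[2])^2), ]
  expect_lt(sqrt(sum((pose@tip - mid)^2)), 2)
  # a user point already on the band is returned unchanged
  onBand <- band[1, ]
  pose2 <- docTarget(f$labels, fr, userPoint = fromPlate(fr, onBand))
  expect_equal(pose2@tip, unname(onBand), tolerance = 1e-6)
  # absent class errors
  empty <- LabelMap(matrix(0L, 8, 8))
  expect_error(docTarget(empty, fr), "site not found")
})

test_that("hindbrain poses encode the start point and direction", {
  p <- hindbrainPose(c(0, 0), c(1, 0))
  expect_equal(p@angleDeg, 0)
  p2 <- hindbrainPose(c(0, 0), c(0, 1))
  expect_equal(p2@angleDeg, 90)   # +y is downward; angles turn toward +y
  p3 <- hindbrainPose(c(5, 5), c(2, 5))
  expect_equal(p3@angleDeg, 180)
  expect_error(hindbrainPose(c(3, 3), c(3, 3)), "coincide")
})

test_that("PVS poses respect the angle range and sit on the upper border", {
  f <- segmentedLarva(53)
  lm <- landmarkCentroids(f$labels)
  fr <- buildSkewedFrame(lm)
  pvsMask <- expandMask(regionMasks(f$larva)$perivitelline_space, c(256, 256))
  bodyMask <- expandMask(regionMasks(f$larva)$body, c(256, 256))
  for (ang in c(30, 45, 60)) {
    pose <- pvsPose(f$labels, fr, ang)
    expect_true(pvsMask[pose@tip[2] + 1, pose@tip[1] + 1])
    expect_true(bodyMask[pose@tip[2] + 1, pose@tip[1] + 1])
  }
  expect_error(pvsPose(f$labels, fr, 75), "30, 60")
  expect_error(pvsPose(f$labels, fr, 20), "30, 60")
})

test_that("site targets land inside their ground-truth masks across many larvae", {
  hits <- 0L; total <- 0L
  for (seed in 1:25) {
    f <- segmentedLarva(seed, size = 224L)
    lm <- landmarkCentroids(f$labels)
    fr <- buildSkewedFrame(lm)
    doc <- docTarget(f$labels, fr)
    pvs <- pvsPose(f$labels, fr, 45)
    docMask <- expandMask(regionMasks(f$larva)$duct_of_cuvier, c(224, 224))
    pvsMask <- expandMask(regionMasks(f$larva)$perivitelline_space, c(224, 224))
    total <- total + 2L
    hits <- hits + docMask[doc@tip[2] + 1, doc@tip[1] + 1] +
      pvsMask[pvs@tip[2] + 1, pvs@tip[1] + 1]
  }
  expect_identical(hits, total)
})
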