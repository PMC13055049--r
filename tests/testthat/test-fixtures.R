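# Synthetic fixture generators: determinism, geometry and ground-truth
# consistency.

test_that("plate generation is seeded, reproducible and well-formed", {
  p1 <- generatePlate(nLarvae = 4, imageSize = c(420, 420), seed = 7)
  p2 <- generatePlate(nLarvae = 4, imageSize = c(420, 420), seed = 7)
  expect_identical(plateImage(p1), plateImage(p2))
  expect_identical(labelRaster(plateTruth(p1)), labelRaster(plateTruth(p2)))
  expect_length(plateLarvae(p1), 4L)
  p3 <- generatePlate(nLarvae = 4, imageSize = c(420, 420), seed = 8)
  expect_false(identical(plateImage(p1), plateImage(p3)))
})

test_that("a single larva produces one connected body component in truth", {
  p <- generatePlate(nLarvae = 1, imageSize = c(256, 256), seed = 3,
                     noiseSd = 0)
  body <- labelRaster(plateTruth(p)) != 0L
  comp <- labelComponents(body)
  expect_identical(max(comp), 1L)
})

test_that("region masks are disjoint, contained in the body and match landmarks", {
  p <- generatePlate(nLarvae = 3, imageSize = c(420, 420), seed = 11,
                     noiseSd = 0)
  size <- c(420, 420)
  for (lar in plateLarvae(p)) {
    masks <- lapply(regionMasks(lar), expandMask, imageSize = size)
    # eye / yolk / swim bladder pairwise disjoint, each inside the body
    for (nm in c("eye", "yolk", "swim_bladder"))
      expect_true(all(!(masks[[nm]] & !masks$body)))
    expect_false(any(masks$eye & masks$yolk))
    expect_false(any(masks$eye & masks$swim_bladder))
    expect_false(any(masks$yolk & masks$swim_bladder))
    # landmarks equal the arithmetic centroids of their masks
    for (nm in names(masks)) {
      idx <- which(masks[[nm]], arr.ind = TRUE)
      ctr <- c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)
      expect_equal(unname(larvaLandmarks(lar)[[nm]]), unname(ctr),
                   tolerance = 1e-12)
    }
  }
})

test_that("rasterizing region masks with the priority rule reproduces truth", {
  p <- generatePlate(nLarvae = 2, imageSize = c(360, 360), seed = 19,
                     noiseSd = 0)
  classes <- anatomyClasses()
  rebuilt <- matrix(0L, 360, 360)
  paintOrder <- rev(classPriority())
  paintOrder <- paintOrder[paintOrder != "background"]
  for (lar in plateLarvae(p)) {
    for (cls in paintOrder) {
      m <- expandMask(regionMasks(lar)[[cls]], c(360, 360))
      rebuilt[m] <- match(cls, classes) - 1L
    }
  }
  expect_identical(rebuilt, labelRaster(plateTruth(p)))
})

test_that("over-dense plates raise a capacity error", {
  expect_error(generatePlate(nLarvae = 30, imageSize = c(220, 220), seed = 1),
               "capacity")
  expect_error(generatePlate(nLarvae = 1, imageSize = c(60, 60), seed = 1),
               "too small")
})

test_that("blood-flow sequences are static without particles and seeded", {
  vm <- syntheticVesselMask(c(48, 48))
  still <- generateBloodflowSequence(vm, nFrames = 6, particleDensity = 0,
                                     seed = 2, noiseSd = 0)
  fr <- frameArray(still$sequence)
  expect_equal(sum(abs(fr[, , -1] - fr[, , -6])), 0)
  s1 <- generateBloodflowSequence(vm, seed = 5)
  s2 <- generateBloodflowSequence(vm, seed = 5)
  expect_identical(frameArray(s1$sequence), frameArray(s2$sequence))
  expect_error(generateBloodflowSequence(matrix(FALSE, 10, 10)), "empty")
  expect_error(generateBloodflowSequence(vm, nFrames = 1), "2 frames")
})

test_that("moving particles change pixels only inside the vessel", {
  vm <- syntheticVesselMask(c(48, 48))
  res <- generateBloodflowSequence(vm, nFrames = 8, particleDensity = 0.05,
                                   seed = 9, noiseSd = 0)
  fr <- frameArray(res$sequence)
  diffSum <- matrix(0, 48, 48)
  for (t in 1:7) diffSum <- diffSum + abs(fr[, , t + 1] - fr[, , t])
  expect_gt(sum(diffSum[vm]), 0)
  expect_equal(sum(diffSum[!vm]), 0)
})

test_that("focal stacks have a unimodal sharpness profile peaking at the target", {
  fs <- generateFocalStack(peakIndex = 5, nSteps = 11, noiseSd = 0, seed = 2)
  sc <- stackSharpness(fs$sequence)
  expect_identical(which.max(sc) - 1L, 5L)
  expect_true(all(diff(sc[1:6]) > 0))
  expect_true(all(diff(sc[6:11]) < 0))
  # boundary case: peak at 0 gives a monotone decreasing profile
  fs0 <- generateFocalStack(peakIndex = 0, nSteps = 7, noiseSd = 0, seed = 2)
  expect_true(all(diff(stackSharpness(fs0$sequence)) < 0))
  expect_error(generateFocalStack(1, 2), "at least 3")
  expect_error(generateFocalStack(7, 5), "within")
  s1 <- generateFocalStack(3, 7, seed = 4)
  s2 <- generateFocalStack(3, 7, seed = 4)
  expect_identical(frameArray(s1$sequence), frameArray(s2$sequence))
})

test_that("puncture sequences drift then jump at the annotated frame", {
  res <- generatePunctureSequence(punctureFrame = 17, driftPx = 0.5,
                                  jumpPx = 6, seed = 4)
  expect_identical(res$event$index, 17L)
  anchors <- seedAnchors(frameArray(res$sequence)[, , 1], n = 6)
  anchors <- trackSequence(anchors, res$sequence)
  meds <- apply(anchorDisplacements(anchors), 1, median, na.rm = TRUE)
  expect_gt(meds[17], 5)
  expect_true(all(meds[1:16] < 1))
  expect_error(generatePunctureSequence(10, 2, 2, seed = 1), "exceed")
  expect_error(generatePunctureSequence(30, 0.5, 6, seed = 1, nFrames = 20),
               "within the sequence")
  a <- generatePunctureSequence(5, 0.5, 4, seed = 8)
  b <- generatePunctureSequence(5, 0.5, 4, seed = 8)
  expect_identical(frameArray(a$sequence), frameArray(b$sequence))
})

test_that("droplet images render the requested disk geometry", {
  res <- generateDropletImage(diameterUm = 100, scaleUmPerPx = 2, seed = 1,
                              noiseSd = 0)
  img <- res$image
  # 50 px disk: dark pixel count close to the disk area
  dark <- sum(img < 0.5)
  expect_equal(dark, pi * 25^2, tolerance = 0.02)
  # degenerate one-pixel droplet still renders something dark
  tiny <- generateDropletImage(2, 2, seed = 1, noiseSd = 0)
  expect_lt(min(tiny$image), 0.6)
  expect_error(generateDropletImage(500, 1, imageSize = c(100, 100)),
               "larger than the image")
  a <- generateDropletImage(80, 2, seed = 3)
  b <- generateDropletImage(80, 2, seed = 3)
  expect_identical(a$image, b$image)
})
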