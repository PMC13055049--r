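#' @include utils.R
NULL

# ---------------------------------------------------------------------------
# Stylized 2-dpf larva template, in local coordinates with the body axis
# along x (head toward +x) and the ventral side toward +y. The template is
# deliberately schematic (ellipses, disks, a ring arc): the pipeline tests
# need geometry and contrast, not photorealism. All regions are contained
# in the body ellipse and the eye/yolk/swim-bladder regions are pairwise
# disjoint by construction.
# ---------------------------------------------------------------------------

larvaGeometry <- function() {
  list(
    bodyA = 46, bodyB = 16,                 # body semi-axes (px)
    eyeX = 30, eyeY = 6, eyeR = 3.5,        # two eye disks at (eyeX, +/-eyeY)
    yolkX = 6, yolkY = 3, yolkR = 9,        # yolk disk
    sbX = -14, sbY = -2, sbA = 7, sbB = 4,  # swim bladder ellipse
    pvsOuter = 12,                          # perivitelline ring outer radius
    docOuter = 11.5, docDy = -4,            # duct-of-Cuvier arc on the yolk margin
    hbX = 21, hbY = -3, hbR = 4,            # hindbrain disk
    boundR = 49                             # bounding radius for placement
  )
}

#' Per-class paint intensities of the synthetic bright-field renderer
#'
#' Each anatomy class is painted at a distinct gray level on the bright
#' agarose background, so a pixel-wise nearest-level classifier recovers
#' the ground truth exactly on noise-free renders (see
#' [templateSegmenter()]).
#'
#' @return named numeric vector of intensities in [0, 1].
#' @export
paintLevels <- function() {
  c(background = 0.88, body = 0.62, eye = 0.10, yolk = 0.45,
    swim_bladder = 0.30, perivitelline_space = 0.53,
    duct_of_cuvier = 0.20, hindbrain = 0.71)
}

# Evaluate the template region predicates at local coordinates (xl, yl).
# Returns a named list of logical vectors; every region is intersected
# with the body so containment holds by construction.
larvaRegionPredicates <- function(xl, yl) {
  g <- larvaGeometry()
  body <- (xl / g$bodyA)^2 + (yl / g$bodyB)^2 <= 1
  eye <- (((xl - g$eyeX)^2 + (yl - g$eyeY)^2 <= g$eyeR^2) |
            ((xl - g$eyeX)^2 + (yl + g$eyeY)^2 <= g$eyeR^2)) & body
  d2 <- (xl - g$yolkX)^2 + (yl - g$yolkY)^2
  yolk <- d2 <= g$yolkR^2 & body
  sb <- ((xl - g$sbX) / g$sbA)^2 + ((yl - g$sbY) / g$sbB)^2 <= 1 & body
  ring <- d2 > g$yolkR^2
  pvs <- ring & d2 <= g$pvsOuter^2 & (yl - g$yolkY) > 0 & body
  doc <- ring & d2 <= g$docOuter^2 & (yl - g$yolkY) < g$docDy & body
  hb <- ((xl - g$hbX)^2 + (yl - g$hbY)^2 <= g$hbR^2) & body
  list(body = body, eye = eye, yolk = yolk, swim_bladder = sb,
       perivitelline_space = pvs, duct_of_cuvier = doc, hindbrain = hb)
}

# Render one larva into bounding-box-cropped region masks.
# Returns list(masks = named list of logical matrices with attr "offset"
# = c(x0, y0) 0-based, landmarks = named list of plate points).
renderLarva <- function(position, headingDeg, imageSize) {
  g <- larvaGeometry()
  W <- imageSize[1]; H <- imageSize[2]
  R <- ceiling(g$boundR) + 1L
  x0 <- max(0L, floor(position[1]) - R); x1 <- min(W - 1L, ceiling(position[1]) + R)
  y0 <- max(0L, floor(position[2]) - R); y1 <- min(H - 1L, ceiling(position[2]) + R)
  xs <- x0:x1; ys <- y0:y1
  gx <- matrix(rep(xs, each = length(ys)), nrow = length(ys))
  gy <- matrix(rep(ys, times = length(xs)), nrow = length(ys))
  th <- headingDeg * pi / 180
  dx <- gx - position[1]; dy <- gy - position[2]
  xl <- cos(th) * dx + sin(th) * dy     # rotate by -heading into local frame
  yl <- -sin(th) * dx + cos(th) * dy
  preds <- larvaRegionPredicates(as.vector(xl), as.vector(yl))
  masks <- lapply(preds, function(p) {
    m <- matrix(p, nrow = length(ys))
    attr(m, "offset") <- c(x0, y0)
    m
  })
  landmarks <- lapply(masks, function(m) {
    if (!any(m)) return(c(NA_real_, NA_real_))
    maskCentroid(m) + attr(m, "offset")
  })
  list(masks = masks, landmarks = landmarks)
}

#' Expand a bounding-box-cropped region mask to full image size
#'
#' Region masks of a \linkS4class{SyntheticLarva} are stored cropped to the
#' larva's bounding box with a 0-based \code{offset} attribute; this helper
#' places the crop into a full plate-sized logical raster.
#'
#' @param mask cropped logical mask with an \code{offset} attribute.
#' @param imageSize c(width, height) of the plate in pixels.
#' @return plate-sized logical matrix.
#' @export
expandMask <- function(mask, imageSize) {
  out <- matrix(FALSE, imageSize[2], imageSize[1])
  off <- attr(mask, "offset")
  out[off[2] + seq_len(nrow(mask)), off[1] + seq_len(ncol(mask))] <- mask
  out
}

#' Generate a synthetic bright-field plate of larvae with ground truth
#'
#' Places \code{nLarvae} stylized larvae at seeded random positions and
#' headings on a bright agarose-like background, guaranteeing a minimum
#' separation between animals (injection plates are prepared so that
#' larvae do not touch). Each anatomy region is painted at its own gray
#' level ([paintLevels()]) and the exact per-pixel ground truth is
#' returned alongside the image.
#'
#' @param nLarvae number of larvae (default 20, the usual batch size per
#'   plate).
#' @param imageSize c(width, height) in pixels.
#' @param seed integer seed; the same seed reproduces the plate bit for bit.
#' @param marginPx minimum gap between larva bounding circles.
#' @param noiseSd standard deviation of the additive Gaussian sensor noise
#'   (clipped to [0, 1]).
#' @param maxRetries placement attempts per larva before giving up with a
#'   capacity error.
#' @return a \linkS4class{SyntheticPlate}.
#' @export
generatePlate <- function(nLarvae = 20L, imageSize = c(1024L, 1024L),
                          seed = 1L, marginPx = 8, noiseSd = 0.005,
                          maxRetries = 200L) {
  stopifnot(nLarvae >= 1L)
  g <- larvaGeometry()
  W <- as.integer(imageSize[1]); H <- as.integer(imageSize[2])
  R <- g$boundR
  if (W - 1 - 2 * R < 0 || H - 1 - 2 * R < 0)
    stop("image too small to place a larva")
  lv <- paintLevels()
  classes <- anatomyClasses()
  withSeed(seed, {
    centers <- matrix(numeric(0), ncol = 2)
    headings <- numeric(0)
    for (i in seq_len(nLarvae)) {
      placed <- FALSE
      for (try in seq_len(maxRetries)) {
        cx <- runif(1, R, W - 1 - R)
        cy <- runif(1, R, H - 1 - R)
        h <- runif(1, 0, 360)
        if (nrow(centers) == 0 ||
            all((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2 >=
                  (2 * R + marginPx)^2)) {
          centers <- rbind(centers, c(cx, cy))
          headings <- c(headings, h)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf("plate capacity exceeded: placed %d of %d larvae without contact",
                     i - 1L, nLarvae))
    }
    image <- matrix(lv[["background"]], H, W)
    truth <- matrix(0L, H, W)
    # painting order is the reverse of the class priority, so that more
    # specific regions overwrite less specific ones
    paintOrder <- rev(classPriority())
    paintOrder <- paintOrder[paintOrder != "background"]
    larvae <- vector("list", nLarvae)
    for (i in seq_len(nLarvae)) {
      rend <- renderLarva(centers[i, ], headings[i], c(W, H))
      for (cls in paintOrder) {
        m <- rend$masks[[cls]]
        off <- attr(m, "offset")
        rows <- off[2] + seq_len(nrow(m)); cols <- off[1] + seq_len(ncol(m))
        sub <- image[rows, cols]; sub[m] <- lv[[cls]]
        image[rows, cols] <- sub
        subT <- truth[rows, cols]; subT[m] <- match(cls, classes) - 1L
        truth[rows, cols] <- subT
      }
      larvae[[i]] <- new("SyntheticLarva", position = centers[i, ],
                         headingDeg = headings[i],
                         regionMasks = rend$masks,
                         landmarks = rend$landmarks)
    }
    if (noiseSd > 0)
      image <- clampValues(image + matrix(rnorm(W * H, 0, noiseSd), H, W))
    new("SyntheticPlate", image = image, larvae = larvae,
        truth = LabelMap(truth, classes), seed = as.integer(seed))
  })
}

#' Deterministic synthetic vessel mask
#'
#' A gently curved band (sine-shaped centerline) used as the vessel
#' geometry for blood-flow videos.
#'
#' @param imageSize c(width, height) in pixels.
#' @param widthPx band width in pixels.
#' @param amplitude vertical amplitude of the centerline as a fraction of
#'   the image height.
#' @return logical matrix marking vessel pixels.
#' @export
syntheticVesselMask <- function(imageSize = c(64L, 64L), widthPx = 3,
                                amplitude = 0.15) {
  W <- imageSize[1]; H <- imageSize[2]
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), times = W), H, W)
  center <- H / 2 + amplitude * H * sin(2 * pi * xs / W)
  abs(ys - center) <= widthPx / 2
}

# Order vessel pixels into a centerline polyline along the principal axis.
vesselCenterline <- function(vesselMask) {
  idx <- which(vesselMask, arr.ind = TRUE)
  pts <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
  ctr <- colMeans(pts)
  cv <- stats::cov(pts)
  e1 <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  t <- (pts[, 1] - ctr[1]) * e1[1] + (pts[, 2] - ctr[2]) * e1[2]
  bin <- round(t - min(t))
  agg <- rowsum(pts, group = bin)
  cnt <- as.vector(table(bin))
  cl <- agg / cnt
  cl[order(as.numeric(rownames(agg))), , drop = FALSE]
}

#' Generate a particle-flow vessel video
#'
#' Emulates the short coaxial-illumination videos in which flowing blood
#' cells appear as dark moving particles inside an otherwise static
#' scene: frames share a static speckled background, dark particles
#' advance along the vessel centerline (wrapping at the ends), and pixels
#' outside the vessel mask change only through seeded sensor noise.
#'
#' @param vesselMask logical matrix marking vessel pixels; must be
#'   non-empty.
#' @param nFrames number of frames (default 10, the length of the
#'   recorded blood-flow videos).
#' @param particleDensity particles per centerline pixel (0 gives a fully
#'   static scene).
#' @param seed integer seed.
#' @param speedPx particle advance per frame along the centerline.
#' @param noiseSd additive Gaussian sensor noise.
#' @param darkening intensity drop of a particle relative to background.
#' @return list with elements \code{sequence} (a
#'   \linkS4class{FrameSequence}) and \code{vesselMask}.
#' @export
generateBloodflowSequence <- function(vesselMask, nFrames = 10L,
                                      particleDensity = 0.08, seed = 1L,
                                      speedPx = 2, noiseSd = 0.005,
                                      darkening = 0.35) {
  if (!any(vesselMask)) stop("vessel mask is empty")
  if (nFrames < 2L) stop("at least 2 frames are required")
  H <- nrow(vesselMask); W <- ncol(vesselMask)
  cl <- vesselCenterline(vesselMask)
  nBins <- nrow(cl)
  withSeed(seed, {
    background <- clampValues(0.80 + matrix(rnorm(H * W, 0, 0.02), H, W),
                              0.05, 0.95)
    nP <- round(particleDensity * nBins)
    if (nP > 0) {
      spacing <- nBins / nP
      s0 <- (seq_len(nP) - 1) * spacing + runif(nP, 0, spacing)
    } else s0 <- numeric(0)
    frames <- array(0, dim = c(H, W, nFrames))
    for (t in seq_len(nFrames) - 1L) {
      fr <- background
      if (nP > 0) {
        for (p in seq_len(nP)) {
          b <- floor((s0[p] + speedPx * t) %% nBins) + 1L
          cx <- cl[b, 1]; cy <- cl[b, 2]
          xs <- max(0, floor(cx - 2)):min(W - 1, ceiling(cx + 2))
          ys <- max(0, floor(cy - 2)):min(H - 1, ceiling(cy + 2))
          for (x in xs) for (y in ys) {
            if ((x - cx)^2 + (y - cy)^2 <= 1.5^2 && vesselMask[y + 1, x + 1])
              fr[y + 1, x + 1] <- background[y + 1, x + 1] - darkening
          }
        }
      }
      if (noiseSd > 0)
        fr <- fr + matrix(rnorm(H * W, 0, noiseSd), H, W)
      frames[, , t + 1L] <- clampValues(fr)
    }
    list(sequence = FrameSequence(frames, kind = "time"),
         vesselMask = vesselMask)
  })
}

#' Generate a focal stack with a known sharpness peak
#'
#' Produces a z-stack of one seeded random texture blurred by a Gaussian
#' whose width grows linearly with the distance from \code{peakIndex}, so
#' that any reasonable focus measure is unimodal with its maximum at the
#' peak (exactly so at \code{noiseSd = 0}).
#'
#' @param peakIndex 0-based index of the in-focus step; must satisfy
#'   \code{0 <= peakIndex < nSteps}.
#' @param nSteps number of z steps (at least 3).
#' @param noiseSd additive Gaussian noise per frame.
#' @param seed integer seed.
#' @param size image edge length in pixels.
#' @return list with elements \code{sequence} (kind "z") and \code{event}
#'   (a ground-truth event list with kind "focus_peak" and the 0-based
#'   index).
#' @export
generateFocalStack <- function(peakIndex, nSteps, noiseSd = 0, seed = 1L,
                               size = 64L) {
  if (nSteps < 3L) stop("a focal stack needs at least 3 steps")
  if (peakIndex < 0 || peakIndex >= nSteps)
    stop("peakIndex must lie within [0, nSteps)")
  withSeed(seed, {
    base <- matrix(runif(size * size, 0.2, 0.8), size, size)
    frames <- array(0, dim = c(size, size, nSteps))
    for (i in seq_len(nSteps) - 1L) {
      sigma <- 0.4 + 0.7 * abs(i - peakIndex)
      fr <- as.matrix(EBImage::gblur(base, sigma = sigma))
      if (noiseSd > 0) fr <- fr + matrix(rnorm(size * size, 0, noiseSd), size, size)
      frames[, , i + 1L] <- clampValues(fr)
    }
    list(sequence = FrameSequence(frames, kind = "z"),
         event = list(kind = "focus_peak", index = as.integer(peakIndex)))
  })
}

#' Generate a needle-approach sequence with a known puncture frame
#'
#' A textured tissue patch translates by \code{driftPx} per frame while
#' the needle pushes the skin; at \code{punctureFrame} the skin retracts
#' more rapidly, which appears as a sudden displacement of
#' \code{jumpPx} against the drift direction.
#'
#' @param punctureFrame 0-based frame index of the puncture (>= 2).
#' @param driftPx per-frame drift displacement (>= 0).
#' @param jumpPx puncture displacement; must exceed \code{driftPx}.
#' @param seed integer seed.
#' @param nFrames sequence length; default \code{punctureFrame + 7}.
#' @param size image edge length in pixels.
#' @param noiseSd additive Gaussian noise per frame.
#' @return list with elements \code{sequence} and \code{event} (kind
#'   "puncture", 0-based index).
#' @export
generatePunctureSequence <- function(punctureFrame, driftPx, jumpPx,
                                     seed = 1L, nFrames = NULL, size = 64L,
                                     noiseSd = 0) {
  if (!(jumpPx > driftPx) || driftPx < 0)
    stop("jumpPx must exceed driftPx and driftPx must be >= 0")
  if (punctureFrame < 2L) stop("punctureFrame must be >= 2")
  if (is.null(nFrames)) nFrames <- as.integer(punctureFrame + 7L)
  if (punctureFrame >= nFrames)
    stop("punctureFrame must lie within the sequence")
  margin <- ceiling(jumpPx + driftPx * nFrames) + 4L
  big <- size + 2L * margin
  withSeed(seed, {
    base <- as.matrix(EBImage::gblur(matrix(runif(big * big), big, big),
                                     sigma = 1.2))
    base <- 0.2 + 0.6 * (base - min(base)) / (max(base) - min(base))
    frames <- array(0, dim = c(size, size, nFrames))
    xs0 <- rep(0:(size - 1), each = size)
    ys0 <- rep(0:(size - 1), times = size)
    for (t in seq_len(nFrames) - 1L) {
      d <- driftPx * t - if (t >= punctureFrame) jumpPx else 0
      fr <- matrix(bilinearSample(base, xs0 + margin + d, ys0 + margin),
                   size, size)
      if (noiseSd > 0) fr <- fr + matrix(rnorm(size * size, 0, noiseSd), size, size)
      frames[, , t + 1L] <- clampValues(fr)
    }
    list(sequence = FrameSequence(frames, kind = "time"),
         event = list(kind = "puncture", index = as.integer(punctureFrame)))
  })
}

#' Generate a droplet-in-oil snapshot
#'
#' Renders a dark, anti-aliased disk (the expelled droplet) on a bright
#' mineral-oil background at a given optical scale.
#'
#' @param diameterUm true droplet diameter in micrometres (> 0).
#' @param scaleUmPerPx optical scale in micrometres per pixel (> 0).
#' @param seed integer seed for the sensor-noise field.
#' @param imageSize c(width, height); defaults to the disk plus a margin.
#' @param noiseSd additive Gaussian noise.
#' @param background,foreground background / droplet intensities.
#' @return list with elements \code{image} and \code{trueDiameterUm}.
#' @export
generateDropletImage <- function(diameterUm, scaleUmPerPx, seed = 1L,
                                 imageSize = NULL, noiseSd = 0.003,
                                 background = 0.85, foreground = 0.15) {
  if (diameterUm <= 0 || scaleUmPerPx <= 0)
    stop("diameter and scale must be positive")
  dPx <- diameterUm / scaleUmPerPx
  if (is.null(imageSize)) imageSize <- rep(ceiling(dPx) + 20L, 2L)
  W <- imageSize[1]; H <- imageSize[2]
  if (dPx > min(W, H) - 2) stop("droplet larger than the image")
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), times = W), H, W)
  dist <- sqrt((xs - cx)^2 + (ys - cy)^2)
  coverage <- clampValues(dPx / 2 + 0.5 - dist)
  img <- background - (background - foreground) * coverage
  withSeed(seed, {
    if (noiseSd > 0) img <- img + matrix(rnorm(W * H, 0, noiseSd), H, W)
  })
  list(image = clampValues(img), trueDiameterUm = diameterUm)
}

#' Generate a sharpness trace with a touchdown jump
#'
#' During the fine descent the top camera focuses just below the needle,
#' so sharpness scores sit on a low baseline until the needle touches the
#' surface, when the score jumps abruptly.
#'
#' @param jumpIndex 0-based step at which the needle touches the surface.
#' @param nSteps trace length.
#' @param baseline baseline sharpness level.
#' @param jumpTo sharpness level from the touchdown step onward.
#' @param noiseSd additive Gaussian noise on the trace.
#' @param seed integer seed.
#' @return list with elements \code{trace} (numeric vector) and
#'   \code{event} (kind "touchdown", 0-based index).
#' @export
generateTouchdownTrace <- function(jumpIndex, nSteps = 20L, baseline = 1,
                                   jumpTo = 5, noiseSd = 0, seed = 1L) {
  if (jumpIndex < 1L || jumpIndex >= nSteps)
    stop("jumpIndex must lie within [1, nSteps)")
  withSeed(seed, {
    tr <- rep(baseline, nSteps)
    tr[(jumpIndex + 1L):nSteps] <- jumpTo
    if (noiseSd > 0) tr <- pmax(tr + rnorm(nSteps, 0, noiseSd), 1e-6)
    list(trace = tr, event = list(kind = "touchdown", index = as.integer(jumpIndex)))
  })
}
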