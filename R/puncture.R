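#' @include focus.R
NULL

# Shi-Tomasi-style corner response: smaller eigenvalue of the smoothed
# structure tensor. High values mark well-textured, trackable locations.
cornerResponse <- function(image) {
  nr <- nrow(image); nc <- ncol(image)
  ix <- matrix(0, nr, nc); iy <- matrix(0, nr, nc)
  ix[, 2:(nc - 1)] <- (image[, 3:nc] - image[, 1:(nc - 2)]) / 2
  iy[2:(nr - 1), ] <- (image[3:nr, ] - image[1:(nr - 2), ]) / 2
  sxx <- as.matrix(EBImage::gblur(ix * ix, sigma = 1))
  syy <- as.matrix(EBImage::gblur(iy * iy, sigma = 1))
  sxy <- as.matrix(EBImage::gblur(ix * iy, sigma = 1))
  tr <- sxx + syy
  dt <- sqrt(pmax((sxx - syy)^2 + 4 * sxy^2, 0))
  (tr - dt) / 2
}

#' Seed anchor points around the needle tip
#'
#' Selects well-textured, trackable locations (corner response above a
#' percentile of the neighbourhood) within a radius of the needle tip.
#' Selection is deterministic: candidates are taken in decreasing
#' response order with a minimum mutual separation.
#'
#' @param image grayscale frame.
#' @param tip needle-tip plate point c(x, y).
#' @param n number of anchor points (>= 4).
#' @param radiusPx seeding radius around the tip.
#' @param responseQuantile percentile of the in-radius corner response a
#'   candidate must exceed.
#' @param minSeparation minimum distance between chosen points.
#' @param patchRadius template patch half-size used later by the tracker.
#' @param searchRadius tracker search half-range in pixels.
#' @param minCorrelation template-match floor below which a point is
#'   flagged lost.
#' @return an \linkS4class{AnchorPointSet}.
#' @export
seedAnchors <- function(image, tip = NULL, n = 8L, radiusPx = 20,
                        responseQuantile = 0.7, minSeparation = 3,
                        patchRadius = 4L, searchRadius = 6L,
                        minCorrelation = 0.5) {
  if (n < 4L) stop("at least 4 anchor points are required")
  nr <- nrow(image); nc <- ncol(image)
  if (is.null(tip)) tip <- c((nc - 1) / 2, (nr - 1) / 2)
  if (tip[1] < 0 || tip[1] > nc - 1 || tip[2] < 0 || tip[2] > nr - 1)
    stop("tip must lie inside the image")
  resp <- cornerResponse(image)
  border <- patchRadius + searchRadius + 1L
  xs <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  ys <- matrix(rep(0:(nr - 1), times = nc), nr, nc)
  inRadius <- (xs - tip[1])^2 + (ys - tip[2])^2 <= radiusPx^2 &
    xs >= border & xs < nc - border & ys >= border & ys < nr - border
  if (!any(inRadius)) stop("insufficient texture: found 0 candidate points")
  thr <- max(stats::quantile(resp[inRadius], responseQuantile), 1e-8)
  cand <- which(inRadius & resp > thr)
  if (length(cand) == 0L)
    stop("insufficient texture: found 0 candidate points")
  ord <- cand[order(resp[cand], decreasing = TRUE)]
  px <- xs[ord]; py <- ys[ord]
  keepX <- numeric(0); keepY <- numeric(0)
  for (i in seq_along(ord)) {
    if (length(keepX) == n) break
    if (length(keepX) == 0 ||
        all((keepX - px[i])^2 + (keepY - py[i])^2 >= minSeparation^2)) {
      keepX <- c(keepX, px[i]); keepY <- c(keepY, py[i])
    }
  }
  if (length(keepX) < n)
    stop(sprintf("insufficient texture: found %d of %d anchor points",
                 length(keepX), n))
  new("AnchorPointSet",
      points = cbind(keepX, keepY, deparse.level = 0),
      displacements = matrix(numeric(0), 0, n),
      lost = rep(FALSE, n),
      state = list(frame = image, patchRadius = as.integer(patchRadius),
                   searchRadius = as.integer(searchRadius),
                   minCorrelation = minCorrelation))
}

# Track one point from the stored previous frame into nextFrame by
# normalized cross-correlation over integer offsets, refined to
# sub-pixel precision by a 1-D quadratic fit per axis.
trackOnePoint <- function(prev, nextFrame, pt, r, s, minCor) {
  nr <- nrow(prev); nc <- ncol(prev)
  cx <- round(pt[1]); cy <- round(pt[2])
  if (cx - r - s < 0 || cx + r + s > nc - 1 ||
      cy - r - s < 0 || cy + r + s > nr - 1)
    return(NULL)
  template <- prev[(cy - r):(cy + r) + 1L, (cx - r):(cx + r) + 1L]
  tv <- as.vector(template)
  if (stats::sd(tv) < 1e-12) return(NULL)
  window <- nextFrame[(cy - r - s):(cy + r + s) + 1L,
                      (cx - r - s):(cx + r + s) + 1L]
  size <- 2 * s + 1
  # all candidate patches as rows of one matrix: NCC against the template
  # becomes a single matrix product instead of per-offset correlation calls
  ws <- 2 * (r + s) + 1L
  patchLen <- (2 * r + 1L)^2
  base <- as.vector(outer(seq_len(2 * r + 1L), 0:(2 * r), function(rr, cc)
    rr + cc * ws))
  shift <- as.vector(outer(0:(2 * s), 0:(2 * s), function(dv, du)
    dv + du * ws))
  P <- matrix(window[outer(shift, base, "+")], nrow = size * size)
  nPix <- patchLen
  mt <- mean(tv); st <- sqrt(sum((tv - mt)^2))
  rs <- rowSums(P)
  cross <- as.vector(P %*% tv) - rs * mt
  sp <- sqrt(pmax(rowSums(P * P) - rs^2 / nPix, 0))
  nccVec <- ifelse(sp < 1e-12, -1, cross / (sp * st))
  ncc <- matrix(nccVec, size, size)  # row = dv + s + 1, col = du + s + 1
  bi <- arrayInd(which.max(ncc), dim(ncc))
  bestCor <- ncc[bi]
  if (bestCor < minCor) return(NULL)
  du <- bi[2] - s - 1L; dv <- bi[1] - s - 1L
  quadRefine <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (!is.finite(den) || den >= 0) return(0)
    clampValues(0.5 * (cm - cp) / den, -0.5, 0.5)
  }
  dx <- 0; dy <- 0
  # an exact integer-offset match needs no sub-pixel refinement
  if (bestCor > 1 - 1e-9) return(list(offset = c(du, dv), cor = bestCor))
  if (bi[2] > 1 && bi[2] < size)
    dx <- quadRefine(ncc[bi[1], bi[2] - 1], bestCor, ncc[bi[1], bi[2] + 1])
  if (bi[1] > 1 && bi[1] < size)
    dy <- quadRefine(ncc[bi[1] - 1, bi[2]], bestCor, ncc[bi[1] + 1, bi[2]])
  list(offset = c(du + dx, dv + dy), cor = bestCor)
}

#' Track anchor points into the next frame
#'
#' Each surviving point is registered from the retained previous frame
#' into \code{nextFrame} by normalized cross-correlation patch matching
#' with sub-pixel refinement; its displacement magnitude is appended to
#' the history. Points whose best match falls below the correlation
#' floor are flagged lost and excluded from statistics.
#'
#' @param anchors an \linkS4class{AnchorPointSet}.
#' @param nextFrame the next grayscale frame.
#' @return the updated \linkS4class{AnchorPointSet}.
#' @export
trackAnchors <- function(anchors, nextFrame) {
  st <- anchors@state
  pts <- anchors@points
  lost <- anchors@lost
  disp <- rep(NA_real_, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (lost[i]) next
    res <- trackOnePoint(st$frame, nextFrame, pts[i, ], st$patchRadius,
                         st$searchRadius, st$minCorrelation)
    if (is.null(res)) {
      lost[i] <- TRUE
      next
    }
    pts[i, ] <- pts[i, ] + res$offset
    disp[i] <- sqrt(sum(res$offset^2))
  }
  st$frame <- nextFrame
  new("AnchorPointSet", points = pts,
      displacements = rbind(anchors@displacements, disp),
      lost = lost, state = st)
}

#' Track anchors through a whole sequence
#'
#' @param anchors an \linkS4class{AnchorPointSet} seeded on frame 0.
#' @param seq the \linkS4class{FrameSequence}; frames 1..T-1 are tracked.
#' @return the final \linkS4class{AnchorPointSet}; displacement row t
#'   holds the movement into frame t (0-based).
#' @export
trackSequence <- function(anchors, seq) {
  fr <- frameArray(seq)
  for (t in 2:dim(fr)[3])
    anchors <- trackAnchors(anchors, fr[, , t])
  anchors
}

#' Detect skin puncture from anchor displacement history
#'
#' While the needle pushes the skin the anchor points move collectively
#' in small increments; at puncture the skin retracts more rapidly and
#' the collective (median) displacement jumps. The event fires at the
#' first frame whose median displacement reaches \code{k} times the
#' median of all prior per-frame medians, subject to an absolute floor.
#'
#' @param anchors a tracked \linkS4class{AnchorPointSet} with at least 3
#'   frames of history.
#' @param k jump factor relative to the prior median (must exceed 1).
#' @param floorPx absolute displacement floor in pixels.
#' @return list with \code{kind} ("puncture" or "none"), 0-based
#'   \code{frameIndex}, the triggering \code{statistic} and
#'   \code{method = "anchor"}.
#' @export
detectPunctureAnchor <- function(anchors, k = 4, floorPx = 2) {
  if (k <= 1) stop("jump factor k must exceed 1")
  D <- anchors@displacements
  if (nrow(D) < 3L) stop("at least 3 frames of history are required")
  meds <- apply(D, 1, stats::median, na.rm = TRUE)
  for (t in 2:length(meds)) {
    prior <- meds[seq_len(t - 1L)]
    thr <- max(k * stats::median(prior, na.rm = TRUE), floorPx)
    if (is.finite(meds[t]) && meds[t] >= thr)
      return(list(kind = "puncture", frameIndex = t, statistic = meds[t],
                  method = "anchor"))
  }
  list(kind = "none", frameIndex = NA_integer_, statistic = NA_real_,
       method = "anchor")
}

#' One-call anchor-based puncture detection on a sequence
#'
#' Seeds anchors near the needle tip on the first frame, tracks them
#' through the sequence and applies the collective-jump detector.
#'
#' @param seq a \linkS4class{FrameSequence}.
#' @param tip needle-tip point; defaults to the image center.
#' @param n number of anchor points.
#' @param k jump factor.
#' @param floorPx absolute displacement floor.
#' @param ... further arguments to [seedAnchors()].
#' @return a puncture event list as from [detectPunctureAnchor()].
#' @export
detectPuncture <- function(seq, tip = NULL, n = 6L, k = 4, floorPx = 2, ...) {
  fr <- frameArray(seq)
  anchors <- seedAnchors(fr[, , 1], tip = tip, n = n, ...)
  anchors <- trackSequence(anchors, seq)
  detectPunctureAnchor(anchors, k = k, floorPx = floorPx)
}

#' Build sliding frame triplets
#'
#' For each frame t >= 2 a three-channel image is formed from frames
#' t-2, t-1 and t in chronological channel order — the input
#' representation of the puncture classification network.
#'
#' @param seq a \linkS4class{FrameSequence} with at least 3 frames
#'   (fewer yield an empty list).
#' @return list of triplets; each a list with \code{channels}
#'   (H x W x 3 array) and 0-based \code{index} t.
#' @export
buildTriplets <- function(seq) {
  fr <- frameArray(seq)
  n <- dim(fr)[3]
  if (n < 3L) return(list())
  lapply(2:(n - 1L) + 1L, function(t) {
    list(channels = fr[, , (t - 2L):t, drop = FALSE], index = t - 1L)
  })
}

#' Score a frame triplet with a pluggable puncture classifier
#'
#' @param model function mapping a triplet to a puncture probability in
#'   [0, 1] (a trained toy network, or an oracle stub in tests).
#' @param triplet a triplet as produced by [buildTriplets()].
#' @return the score.
#' @export
classifyPuncture <- function(model, triplet) {
  ch <- triplet$channels
  if (length(dim(ch)) != 3L || dim(ch)[3] != 3L)
    stop("triplet must carry exactly 3 chronological channels")
  score <- model(triplet)
  if (length(score) != 1L || !is.finite(score) || score < 0 || score > 1)
    stop("classifier must return a single score in [0, 1]")
  score
}

#' Classifier-based puncture detection over a sequence
#'
#' @param model pluggable classifier (see [classifyPuncture()]).
#' @param seq a \linkS4class{FrameSequence}.
#' @param cutoff decision cutoff on the per-triplet score.
#' @return event list with \code{method = "classifier"}; the frame index
#'   is the triplet index t of the first score above the cutoff.
#' @export
detectPunctureClassifier <- function(model, seq, cutoff = 0.5) {
  for (tr in buildTriplets(seq)) {
    s <- classifyPuncture(model, tr)
    if (s >= cutoff)
      return(list(kind = "puncture", frameIndex = tr$index, statistic = s,
                  method = "classifier"))
  }
  list(kind = "none", frameIndex = NA_integer_, statistic = NA_real_,
       method = "classifier")
}

#' Train a toy logistic puncture classifier on labelled triplets
#'
#' A deliberately small stand-in for the classification network: logistic
#' regression on summary features of the inter-channel differences
#' (mean and upper-quantile motion, and the recent-to-earlier motion
#' ratio). Sufficient for the synthetic drift-then-jump sequences;
#' pluggable behind the same interface as any stronger model.
#'
#' @param triplets list of triplets (see [buildTriplets()]).
#' @param labels binary vector: 1 for puncture triplets.
#' @return classifier function for [classifyPuncture()].
#' @export
trainTripletClassifier <- function(triplets, labels) {
  featuresOf <- function(tr) {
    ch <- tr$channels
    d1 <- abs(ch[, , 2] - ch[, , 1])
    d2 <- abs(ch[, , 3] - ch[, , 2])
    c(m1 = mean(d1), m2 = mean(d2),
      ratio = mean(d2) / (mean(d1) + 1e-9),
      q = as.numeric(stats::quantile(d2, 0.95)))
  }
  X <- t(vapply(triplets, featuresOf, numeric(4)))
  df <- data.frame(X, y = as.numeric(labels))
  fit <- suppressWarnings(stats::glm(y ~ m1 + m2 + ratio + q, data = df,
                                     family = stats::binomial()))
  function(triplet) {
    f <- as.data.frame(t(featuresOf(triplet)))
    p <- suppressWarnings(stats::predict(fit, newdata = f, type = "response"))
    clampValues(as.numeric(p))
  }
}
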