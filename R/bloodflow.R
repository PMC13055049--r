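#' @include targeting.R
NULL

#' Blood-flow activity map from a short frame sequence
#'
#' A static image cannot capture flowing blood, so a short video is
#' summarized instead: the absolute differences of all subsequent frame
#' pairs are summed per pixel and the sum is normalized by its maximum,
#' yielding values in [0, 1]. An all-static sequence yields an all-zero
#' map. Frames are converted to floating point before differencing so
#' unsigned-integer wraparound cannot occur.
#'
#' @param seq a \linkS4class{FrameSequence} with at least two frames.
#' @return a \linkS4class{BloodFlowMap}.
#' @export
bloodFlowMap <- function(seq) {
  fr <- frameArray(seq)
  n <- dim(fr)[3]
  if (n < 2L) stop("blood-flow mapping needs at least 2 frames")
  acc <- matrix(0, dim(fr)[1], dim(fr)[2])
  for (t in seq_len(n - 1L))
    acc <- acc + abs(fr[, , t + 1L] - fr[, , t])
  m <- max(acc)
  if (m > 0) acc <- acc / m
  new("BloodFlowMap", activity = acc, nFramesUsed = as.integer(n))
}

#' Overlay a blood-flow map in red on the last frame
#'
#' The activity is blended into the red channel of the (grayscale) last
#' frame; green and blue replicate the frame, so flowing blood appears
#' red on the anatomical image.
#'
#' @param map a \linkS4class{BloodFlowMap}.
#' @param lastFrame grayscale matrix of matching size.
#' @param weight blending weight in [0, 1]; at 1, a pixel with activity 1
#'   has a saturated red channel.
#' @return H x W x 3 numeric RGB array.
#' @export
overlayFlow <- function(map, lastFrame, weight = 1) {
  a <- activityMap(map)
  if (!identical(dim(a), dim(lastFrame)))
    stop("activity map and frame dimensions do not match")
  red <- lastFrame + weight * a * (1 - lastFrame)
  out <- array(0, dim = c(dim(a), 3L))
  out[, , 1] <- red
  out[, , 2] <- lastFrame
  out[, , 3] <- lastFrame
  out
}

#' Recover activity from an overlay
#'
#' Inverse of [overlayFlow()] up to quantization: activity is read back
#' from the difference between the red channel and the grayscale frame.
#'
#' @param rgb H x W x 3 array produced by [overlayFlow()].
#' @param weight the blending weight used for the overlay.
#' @return numeric activity matrix.
#' @export
extractOverlayActivity <- function(rgb, weight = 1) {
  gray <- rgb[, , 2]
  denom <- weight * (1 - gray)
  act <- (rgb[, , 1] - gray) / ifelse(denom <= 0, 1, denom)
  clampValues(act)
}
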