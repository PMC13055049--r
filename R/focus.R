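#' @include bloodflow.R
NULL

#' Image sharpness by variance of the Laplacian
#'
#' The classical focus measure used during needle descent: the variance
#' of the discrete 4-neighbour Laplacian response over the image
#' interior. Zero for a constant image, and monotonically decreasing
#' under increasing Gaussian blur of a fixed texture.
#'
#' @param image grayscale numeric matrix (at least 3 x 3).
#' @return non-negative sharpness score.
#' @export
sharpness <- function(image) {
  if (length(image) == 0L) stop("empty image")
  nr <- nrow(image); nc <- ncol(image)
  if (nr < 3L || nc < 3L) stop("image too small for a Laplacian response")
  ctr <- image[2:(nr - 1), 2:(nc - 1)]
  lap <- 4 * ctr - image[1:(nr - 2), 2:(nc - 1)] - image[3:nr, 2:(nc - 1)] -
    image[2:(nr - 1), 1:(nc - 2)] - image[2:(nr - 1), 3:nc]
  stats::var(as.vector(lap))
}

#' Sharpness scores of every frame in a stack
#'
#' @param seq a \linkS4class{FrameSequence}.
#' @return numeric vector of per-frame sharpness scores.
#' @export
stackSharpness <- function(seq) {
  fr <- frameArray(seq)
  vapply(seq_len(dim(fr)[3]), function(i) sharpness(fr[, , i]), numeric(1))
}

#' Detect the sharpness peak during coarse descent
#'
#' Processes the score stream causally, in descent order: once the score
#' has risen and then fallen below the running maximum by the hysteresis
#' fraction for one step, the descent is declared past focus and the
#' argmax index is emitted. An emitted event is never revised by later
#' samples. A stream that never falls (or never rises) yields no event.
#'
#' @param scores numeric vector of sharpness scores in descent order.
#' @param hysteresis relative drop below the running maximum required to
#'   confirm the peak (default 0.05).
#' @return list with \code{kind} ("focus_peak" or "none") and 0-based
#'   \code{stepIndex} (NA when no event).
#' @export
findFocusPeak <- function(scores, hysteresis = 0.05) {
  if (any(!is.finite(scores)) || any(scores < 0))
    stop("scores must be finite and non-negative")
  best <- -Inf; bestIdx <- NA_integer_
  for (i in seq_along(scores)) {
    s <- scores[i]
    if (s > best) {
      best <- s
      bestIdx <- i - 1L
    } else if (bestIdx >= 1L && s < best * (1 - hysteresis)) {
      return(list(kind = "focus_peak", stepIndex = bestIdx))
    }
  }
  list(kind = "none", stepIndex = NA_integer_)
}

#' Detect needle touchdown during fine descent
#'
#' With the focus set just below the needle, the sharpness stays on a low
#' baseline until the needle touches the surface, where it jumps. The
#' event fires causally at the first step whose score reaches
#' \code{threshold} times the rolling-median baseline of the preceding
#' steps.
#'
#' @param scores numeric vector of sharpness scores in descent order.
#' @param threshold relative sharpness jump declaring touchdown; must
#'   exceed 1.
#' @param window rolling-median window (number of preceding steps used as
#'   baseline).
#' @return list with \code{kind} ("touchdown" or "none") and 0-based
#'   \code{stepIndex} (NA when no event).
#' @export
detectTouchdown <- function(scores, threshold = 3, window = 5L) {
  if (threshold <= 1) stop("touchdown threshold must exceed 1")
  n <- length(scores)
  # the detector arms once a minimal baseline history exists; a rolling
  # median over fewer samples is too easily dragged down by noise dips
  warmup <- 3L
  if (n > warmup) {
    for (i in (warmup + 1L):n) {
      lo <- max(1L, i - window)
      baseline <- stats::median(scores[lo:(i - 1L)])
      if (scores[i] >= threshold * max(baseline, 1e-12))
        return(list(kind = "touchdown", stepIndex = i - 1L))
    }
  }
  list(kind = "none", stepIndex = NA_integer_)
}

#' Two-phase needle-descent controller
#'
#' Encodes the descent procedure as an explicit state machine: in state
#' COARSE the camera focuses far below the needle and the head descends
#' until the sharpness trace peaks (the larva surface is in focus); the
#' controller then switches focus to just below the needle tip and
#' enters FINE, descending in smaller steps until a sudden sharpness
#' increase signals touchdown (state TOUCHED).
#'
#' @param coarseScores sharpness trace of the coarse descent.
#' @param fineScores sharpness trace of the fine descent.
#' @param hysteresis peak-confirmation fraction for the coarse phase.
#' @param threshold relative jump for the fine phase.
#' @param window rolling-median window for the fine phase.
#' @return list with final \code{state} ("COARSE", "FINE" or "TOUCHED")
#'   and the \code{focusPeak} / \code{touchdown} events.
#' @export
runDescent <- function(coarseScores, fineScores, hysteresis = 0.05,
                       threshold = 3, window = 5L) {
  state <- "COARSE"
  peak <- findFocusPeak(coarseScores, hysteresis)
  touch <- list(kind = "none", stepIndex = NA_integer_)
  if (identical(peak$kind, "focus_peak")) {
    state <- "FINE"
    touch <- detectTouchdown(fineScores, threshold, window)
    if (identical(touch$kind, "touchdown")) state <- "TOUCHED"
  }
  list(state = state, focusPeak = peak, touchdown = touch)
}
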