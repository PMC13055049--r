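#' @include macro.R
NULL

#' Locate larvae on a plate image in scan order
#'
#' Segments the plate and returns one detection per connected
#' non-background region of sufficient size, ordered the way the robot
#' scans the plate: top to bottom, ties broken left to right, by body
#' centroid. Each detection carries its cropped label map.
#'
#' @param image plate image matrix.
#' @param segmenter pluggable segmenter (image to
#'   \linkS4class{ProbabilityMap}).
#' @param scheme a \linkS4class{TilingScheme}.
#' @param minAreaPx minimum pixel area for a detection.
#' @param padPx crop padding around each detection's bounding box.
#' @return list of detections: each a list with \code{id},
#'   \code{centroid} c(x, y), \code{bbox} c(x0, y0, x1, y1) (0-based,
#'   inclusive) and \code{labels} (cropped \linkS4class{LabelMap}).
#' @export
scanPlate <- function(image, segmenter = templateSegmenter(),
                      scheme = TilingScheme(), minAreaPx = 400L,
                      padPx = 3L) {
  labels <- segmentImage(image, segmenter, scheme)
  r <- labelRaster(labels)
  comp <- labelComponents(r != 0L)
  nComp <- max(comp)
  if (nComp == 0L) return(list())
  dets <- list()
  for (i in seq_len(nComp)) {
    idx <- which(comp == i, arr.ind = TRUE)
    if (nrow(idx) < minAreaPx) next
    px <- idx[, 2] - 1L; py <- idx[, 1] - 1L
    x0 <- max(0L, min(px) - padPx); x1 <- min(ncol(r) - 1L, max(px) + padPx)
    y0 <- max(0L, min(py) - padPx); y1 <- min(nrow(r) - 1L, max(py) + padPx)
    crop <- r[(y0 + 1L):(y1 + 1L), (x0 + 1L):(x1 + 1L), drop = FALSE]
    dets[[length(dets) + 1L]] <- list(
      centroid = c(mean(px), mean(py)), bbox = c(x0, y0, x1, y1),
      labels = LabelMap(crop, classNames(labels)))
  }
  if (length(dets) == 0L) return(list())
  cy <- vapply(dets, function(d) d$centroid[2], numeric(1))
  cx <- vapply(dets, function(d) d$centroid[1], numeric(1))
  dets <- dets[order(cy, cx)]
  for (i in seq_along(dets)) dets[[i]]$id <- i
  dets
}

# Build the per-larva detector context. "oracle" uses the fixture ground
# truth directly; "simulated" generates the optical fixtures and runs the
# actual detectors on them, so a session exercises the full decision
# stack.
makeLarvaContext <- function(larvaSeed, detectors = c("oracle", "simulated"),
                             operator = NULL, larvaId = NA_integer_) {
  detectors <- match.arg(detectors)
  withSeed(larvaSeed, {
    touchIdx <- sample(5:12, 1)
    punctIdx <- sample(8:16, 1)
  })
  if (detectors == "oracle") {
    list(touchdownEvent = list(kind = "touchdown", stepIndex = touchIdx),
         punctureEvent = list(kind = "puncture", frameIndex = punctIdx),
         operator = operator, larvaId = larvaId)
  } else {
    td <- generateTouchdownTrace(touchIdx, nSteps = 20L, noiseSd = 0.1,
                                 seed = larvaSeed + 1L)
    touch <- detectTouchdown(td$trace)
    ps <- generatePunctureSequence(punctIdx, driftPx = 0.5, jumpPx = 6,
                                   seed = larvaSeed + 2L, size = 48L)
    punct <- detectPuncture(ps$sequence)
    list(touchdownEvent = if (touch$kind == "touchdown") touch else NULL,
         punctureEvent = if (punct$kind == "puncture") punct else NULL,
         operator = operator, larvaId = larvaId)
  }
}

#' Run a full injection session over a plate
#'
#' Iterates the larvae in scan order; for each, builds the detector
#' context, executes the macro on the simulated clock, and logs the
#' outcome. The batch time budget is enforced: larvae remaining when the
#' budget is exhausted are marked skipped (anesthetized larvae dry out,
#' so a batch must stay within its time budget). In semi-automated mode
#' the scripted operator callback is consulted at every
#' operator_checkpoint and may abort the current larva; the session then
#' continues with the next one. Per-larva failures are recorded, never
#' raised.
#'
#' @param plate a \linkS4class{SyntheticPlate} (or a plate image matrix).
#' @param macro the \linkS4class{InjectionMacro} to execute per larva.
#' @param mode "automated" or "semi_automated".
#' @param seed integer seed driving the per-larva outcome fixtures and
#'   the survival placeholder.
#' @param site injection-site label recorded per row.
#' @param detectors "oracle" (ground-truth events) or "simulated"
#'   (generate optical fixtures and run the real detectors).
#' @param operator scripted operator callback for semi-automated mode:
#'   \code{function(larvaId, trace)} returning "continue" or "abort".
#' @param budgetSeconds batch time budget on the simulated clock
#'   (default 420 s = 7 min).
#' @param survivalRate placeholder Bernoulli survival probability per
#'   successful injection; survival is a biological outcome the software
#'   cannot compute, so it is modelled explicitly as a placeholder.
#' @param segmenter pluggable segmenter for plate scanning.
#' @param costs per-action simulated time costs.
#' @return a \linkS4class{SessionRecord}.
#' @export
runSession <- function(plate, macro, mode = c("automated", "semi_automated"),
                       seed = 1L, site = "doc_mid",
                       detectors = c("oracle", "simulated"),
                       operator = NULL, budgetSeconds = 420,
                       survivalRate = 0.9,
                       segmenter = templateSegmenter(),
                       costs = actionCosts()) {
  mode <- match.arg(mode)
  detectors <- match.arg(detectors)
  image <- if (is(plate, "SyntheticPlate")) plateImage(plate) else plate
  dets <- scanPlate(image, segmenter)
  rows <- list(); traces <- list()
  clock <- 0
  for (d in dets) {
    if (clock > budgetSeconds) {
      rows[[length(rows) + 1L]] <- data.frame(
        larva_id = d$id, site = site, mode = mode, outcome = "skipped",
        reason = "batch_time_budget", t_start = clock, t_end = clock,
        survived = NA, stringsAsFactors = FALSE)
      traces[length(traces) + 1L] <- list(NULL)
      next
    }
    ctx <- makeLarvaContext(seed + 1000L * d$id, detectors,
                            operator = if (mode == "semi_automated") operator,
                            larvaId = d$id)
    res <- executeMacro(macro, ctx, costs, startTime = clock)
    survived <- NA
    if (res$outcome == "success") {
      survived <- withSeed(seed + 1000L * d$id + 7L,
                           stats::runif(1) < survivalRate)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      larva_id = d$id, site = site, mode = mode, outcome = res$outcome,
      reason = res$reason, t_start = clock, t_end = res$endTime,
      survived = survived, stringsAsFactors = FALSE)
    traces[[length(traces) + 1L]] <- res$trace
    clock <- res$endTime
  }
  records <- if (length(rows)) do.call(rbind, rows) else
    data.frame(larva_id = integer(0), site = character(0),
               mode = character(0), outcome = character(0),
               reason = character(0), t_start = numeric(0),
               t_end = numeric(0), survived = logical(0))
  new("SessionRecord", records = records, traces = traces)
}

#' Summarize a session into throughput and success statistics
#'
#' @param record a \linkS4class{SessionRecord} with at least one row.
#' @return a \linkS4class{SessionSummary}: success rate over injected
#'   (non-skipped) larvae, throughput from the mean simulated per-larva
#'   time, and the placeholder survival rate among successes. The
#'   across-session standard deviation is 0 and flagged
#'   \code{singleSession} when only one session is summarized.
#' @export
summarizeSession <- function(record) {
  rec <- sessionRecords(record)
  if (nrow(rec) == 0L) stop("cannot summarize an empty session")
  injected <- rec[rec$outcome != "skipped", , drop = FALSE]
  if (nrow(injected) == 0L)
    stop("undefined rates: no larvae were injected")
  nSucc <- sum(injected$outcome == "success")
  meanTime <- mean(injected$t_end - injected$t_start)
  surv <- injected$survived[injected$outcome == "success"]
  new("SessionSummary",
      nInjected = nrow(injected),
      successRate = 100 * nSucc / nrow(injected),
      larvaePerHour = 3600 / meanTime,
      survivalRate = if (nSucc > 0) 100 * mean(surv) else 0,
      sdSuccessRate = 0, singleSession = TRUE)
}

#' Mean and standard deviation of success rates across sessions
#'
#' Mirrors the "average" rows of the validation tables: mean value
#' plus-minus the sample standard deviation over sessions.
#'
#' @param records list of \linkS4class{SessionRecord} objects.
#' @return list with \code{meanSuccessRate}, \code{sdSuccessRate} and
#'   \code{nSessions}; the sd of a single session is 0.
#' @export
summarizeSessions <- function(records) {
  rates <- vapply(records, function(r) summarizeSession(r)@successRate,
                  numeric(1))
  list(meanSuccessRate = mean(rates),
       sdSuccessRate = if (length(rates) > 1L) stats::sd(rates) else 0,
       nSessions = length(rates))
}

#' One-tailed Welch comparison of two groups of session rates
#'
#' Two-sample unequal-variance (Welch) t test with
#' Welch-Satterthwaite degrees of freedom and a one-tailed p value,
#' as used to compare the automated mode against manual injection.
#'
#' @param sampleA,sampleB numeric vectors of per-session rates (n >= 2
#'   each).
#' @param alternative "greater" tests mean(A) > mean(B); "less" the
#'   reverse.
#' @param alpha significance level for the flag.
#' @return list with \code{statistic}, \code{df}, \code{p.value} and
#'   \code{significant}. Two zero-variance samples with equal means give
#'   p = 0.5 by convention.
#' @export
compareModes <- function(sampleA, sampleB,
                         alternative = c("greater", "less"), alpha = 0.05) {
  alternative <- match.arg(alternative)
  if (length(sampleA) < 2L || length(sampleB) < 2L)
    stop("each sample needs at least 2 observations")
  va <- stats::var(sampleA); vb <- stats::var(sampleB)
  if (va == 0 && vb == 0) {
    dm <- mean(sampleA) - mean(sampleB)
    if (dm == 0)
      return(list(statistic = 0, df = NA_real_, p.value = 0.5,
                  significant = FALSE))
    favored <- (alternative == "greater") == (dm > 0)
    p <- if (favored) 0 else 1
    return(list(statistic = sign(dm) * Inf, df = NA_real_, p.value = p,
                significant = p < alpha))
  }
  tt <- stats::t.test(sampleA, sampleB, alternative = alternative,
                      var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, significant = tt$p.value < alpha)
}
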