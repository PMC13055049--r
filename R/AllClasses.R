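#' @import methods
NULL

# Conventions used throughout the package:
#  * images are numeric H x W matrices with intensities in [0, 1];
#    mat[y + 1, x + 1] is the pixel at 0-based coordinates (x, y),
#    x rightward, y downward.
#  * points are numeric length-2 vectors c(x, y) in 0-based pixel
#    coordinates; angles are in degrees, measured from +x toward +y
#    (counter-clockwise in the y-down raster convention), normalized
#    to [0, 360).
#  * label rasters store 0-based class indices into the class list;
#    index 0 is always "background".

#' Per-pixel anatomy class raster
#'
#' The segmentation currency of the pipeline: an integer raster in which
#' every pixel carries a 0-based index into an ordered anatomy class list.
#'
#' @slot classes ordered character vector of class names; the raster value
#'   \code{k} denotes \code{classes[k + 1]}.
#' @slot raster integer matrix (rows = y, columns = x) of class indices in
#'   \code{[0, length(classes))}.
#' @exportClass LabelMap
setClass("LabelMap", representation(classes = "character", raster = "matrix"))

setValidity("LabelMap", function(object) {
  r <- object@raster
  n <- length(object@classes)
  if (n < 1L) return("class list must be non-empty")
  if (anyDuplicated(object@classes)) return("class names must be unique")
  if (!is.numeric(r)) return("raster must be numeric (integer class indices)")
  if (any(r != floor(r))) return("raster values must be integers")
  if (min(r) < 0 || max(r) >= n)
    return(sprintf("raster values must lie in [0, %d)", n))
  TRUE
})

#' Per-pixel class score raster
#'
#' A W x H x N score array as produced by a segmentation network:
#' one score per pixel per anatomy class.
#'
#' @slot classes ordered character vector of N class names.
#' @slot scores numeric array of dimension H x W x N; all finite.
#' @exportClass ProbabilityMap
setClass("ProbabilityMap", representation(classes = "character", scores = "array"))

setValidity("ProbabilityMap", function(object) {
  d <- dim(object@scores)
  if (length(d) != 3L) return("scores must be an H x W x N array")
  if (d[3] != length(object@classes))
    return("third dimension must equal the number of classes")
  if (!all(is.finite(object@scores))) return("scores must be finite")
  TRUE
})

#' Tile layout for piecewise segmentation inference
#'
#' Defaults follow the deployment layout of the inference pipeline:
#' 304-pixel square tiles overlapped by 50 pixels in both directions.
#'
#' @slot tileSize tile edge length in pixels.
#' @slot overlap overlap between neighbouring tiles in pixels.
#' @exportClass TilingScheme
setClass("TilingScheme",
         representation(tileSize = "integer", overlap = "integer"),
         prototype(tileSize = 304L, overlap = 50L))

setValidity("TilingScheme", function(object) {
  if (length(object@tileSize) != 1L || length(object@overlap) != 1L)
    return("tileSize and overlap must be scalars")
  if (object@tileSize < 1L) return("tileSize must be positive")
  if (object@overlap < 0L || object@overlap >= object@tileSize)
    return("overlap must satisfy 0 <= overlap < tileSize")
  TRUE
})

#' Time- or z-ordered image stack
#'
#' @slot frames numeric array H x W x T of grayscale frames in [0, 1].
#' @slot kind either \code{"time"} (video) or \code{"z"} (focal stack).
#' @exportClass FrameSequence
setClass("FrameSequence",
         representation(frames = "array", kind = "character"),
         prototype(kind = "time"))

setValidity("FrameSequence", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be an H x W x T array")
  if (d[3] < 1L) return("sequence must contain at least one frame")
  if (!object@kind %in% c("time", "z")) return("kind must be 'time' or 'z'")
  TRUE
})

#' One stylized larva with exact ground truth
#'
#' @slot position plate pixel coordinates c(x, y) of the body centroid.
#' @slot headingDeg orientation in degrees; 0 means facing +x.
#' @slot regionMasks named list of logical plate-sized masks, one per
#'   anatomy class (eye, yolk, swim_bladder, perivitelline_space,
#'   duct_of_cuvier, hindbrain, body).
#' @slot landmarks named list of c(x, y) centroids, one per region.
#' @exportClass SyntheticLarva
setClass("SyntheticLarva",
         representation(position = "numeric", headingDeg = "numeric",
                        regionMasks = "list", landmarks = "list"))

#' A synthetic bright-field plate of larvae with ground truth
#'
#' @slot image bright-field-like numeric matrix in [0, 1].
#' @slot larvae list of \linkS4class{SyntheticLarva}.
#' @slot truth ground-truth \linkS4class{LabelMap}.
#' @slot seed integer seed the plate was generated from.
#' @exportClass SyntheticPlate
setClass("SyntheticPlate",
         representation(image = "matrix", larvae = "list",
                        truth = "LabelMap", seed = "integer"))

setValidity("SyntheticPlate", function(object) {
  if (!identical(dim(object@image), dim(object@truth@raster)))
    return("image and truth raster dimensions must match")
  TRUE
})

#' Anatomical landmark centroids of one larva
#'
#' @slot eyes centroid c(x, y) of the union of both eyes.
#' @slot yolk centroid of the yolk mask.
#' @slot swimBladder centroid of the swim bladder (or perivitelline space).
#' @exportClass LandmarkSet
setClass("LandmarkSet",
         representation(eyes = "numeric", yolk = "numeric",
                        swimBladder = "numeric"))

setValidity("LandmarkSet", function(object) {
  pts <- list(object@eyes, object@yolk, object@swimBladder)
  if (!all(vapply(pts, function(p) length(p) == 2L && all(is.finite(p)), TRUE)))
    return("landmarks must be finite length-2 points")
  if (identical(object@eyes, object@yolk) ||
      identical(object@eyes, object@swimBladder) ||
      identical(object@yolk, object@swimBladder))
    return("landmarks must be pairwise distinct")
  TRUE
})

#' Skewed (non-orthogonal) larva coordinate frame
#'
#' Site coordinates (a, b) map to plate pixels as origin + a*u + b*v.
#' By convention the origin is the eyes centroid, u points to the yolk
#' centroid and v to the swim-bladder centroid.
#'
#' @slot origin plate point c(x, y).
#' @slot u first basis vector (eyes -> yolk).
#' @slot v second basis vector (eyes -> swim bladder).
#' @exportClass SkewedFrame
setClass("SkewedFrame",
         representation(origin = "numeric", u = "numeric", v = "numeric"))

setValidity("SkewedFrame", function(object) {
  if (!all(vapply(list(object@origin, object@u, object@v),
                  function(p) length(p) == 2L && all(is.finite(p)), TRUE)))
    return("origin, u and v must be finite length-2 vectors")
  nu <- sqrt(sum(object@u^2)); nv <- sqrt(sum(object@v^2))
  if (nu == 0 || nv == 0) return("basis vectors must be non-zero")
  cr <- abs(object@u[1] * object@v[2] - object@u[2] * object@v[1])
  if (cr / (nu * nv) < 1e-3) return("basis vectors are collinear (degenerate frame)")
  TRUE
})

#' Needle tip position and yaw for one injection
#'
#' @slot tip plate point c(x, y).
#' @slot angleDeg needle yaw in the plate frame, normalized to [0, 360).
#' @slot site injection-site label.
#' @exportClass NeedlePose
setClass("NeedlePose",
         representation(tip = "numeric", angleDeg = "numeric", site = "character"))

setValidity("NeedlePose", function(object) {
  if (length(object@tip) != 2L || !all(is.finite(object@tip)))
    return("tip must be a finite length-2 point")
  if (object@angleDeg < 0 || object@angleDeg >= 360)
    return("angleDeg must be normalized to [0, 360)")
  TRUE
})

#' Blood-flow activity map
#'
#' @slot activity numeric matrix with values in [0, 1]; high values mark
#'   pixels that changed between subsequent frames (flowing blood).
#' @slot nFramesUsed number of frames the map was computed from.
#' @exportClass BloodFlowMap
setClass("BloodFlowMap",
         representation(activity = "matrix", nFramesUsed = "integer"))

setValidity("BloodFlowMap", function(object) {
  a <- object@activity
  if (!all(is.finite(a))) return("activity must be finite")
  if (min(a) < 0 || max(a) > 1) return("activity must lie within [0, 1]")
  if (object@nFramesUsed < 2L) return("map must be computed from >= 2 frames")
  TRUE
})

#' Tracked anchor points around the needle tip
#'
#' Holds the current point positions, the per-frame displacement history
#' and the tracker state (reference frame and template patches).
#'
#' @slot points n x 2 matrix of current point positions (x, y).
#' @slot displacements frames x n matrix of per-frame displacement
#'   magnitudes in pixels (row t = movement into frame t).
#' @slot lost logical vector flagging points whose match score fell
#'   below the floor; they are excluded from statistics.
#' @slot state internal tracker state (previous frame, patch radius,
#'   search radius, minimum correlation).
#' @exportClass AnchorPointSet
setClass("AnchorPointSet",
         representation(points = "matrix", displacements = "matrix",
                        lost = "logical", state = "list"))

setValidity("AnchorPointSet", function(object) {
  if (nrow(object@points) < 4L) return("at least 4 anchor points are required")
  if (ncol(object@points) != 2L) return("points must be an n x 2 matrix")
  if (length(object@lost) != nrow(object@points))
    return("lost flags must match the number of points")
  if (nrow(object@displacements) > 0 && min(object@displacements, na.rm = TRUE) < 0)
    return("displacements must be non-negative")
  TRUE
})

#' Droplet measurement record
#'
#' @slot diameterPx equivalent-area diameter in pixels.
#' @slot diameterUm diameter in micrometres.
#' @slot volumeNl spherical volume (pi/6) d^3 in nanolitres.
#' @slot circularity moment-based circularity in (0, 1]; 1 for a disk.
#' @slot center droplet centroid c(x, y) in the image.
#' @exportClass DropletMeasurement
setClass("DropletMeasurement",
         representation(diameterPx = "numeric", diameterUm = "numeric",
                        volumeNl = "numeric", circularity = "numeric",
                        center = "numeric"))

setValidity("DropletMeasurement", function(object) {
  if (object@diameterPx <= 0) return("diameter must be positive")
  if (object@circularity <= 0 || object@circularity > 1)
    return("circularity must lie in (0, 1]")
  expect <- (pi / 6) * object@diameterUm^3 * 1e-6
  if (abs(object@volumeNl - expect) > 1e-9 * max(1, expect))
    return("volumeNl must equal (pi/6) * diameterUm^3 in nL")
  TRUE
})

#' Declarative injection macro
#'
#' An ordered list of primitive needle/pressure actions replayed for every
#' larva. Supported actions: approach, descend_coarse, descend_fine,
#' await_touchdown, advance_along_axis, await_puncture, retract, pulse,
#' repeat (with nested steps) and operator_checkpoint.
#'
#' @slot name macro name.
#' @slot steps list of steps; each step is a named list with an
#'   \code{action} element plus action-specific parameters.
#' @exportClass InjectionMacro
setClass("InjectionMacro", representation(name = "character", steps = "list"))

setValidity("InjectionMacro", function(object) {
  acts <- c("approach", "descend_coarse", "descend_fine", "await_touchdown",
            "advance_along_axis", "await_puncture", "retract", "pulse",
            "repeat", "operator_checkpoint")
  check <- function(steps) {
    for (s in steps) {
      if (is.null(s$action) || !s$action %in% acts)
        return(sprintf("unknown macro action '%s'", as.character(s$action)))
      if (identical(s$action, "repeat")) {
        if (is.null(s$k) || s$k < 1) return("repeat requires k >= 1")
        msg <- check(s$steps)
        if (!isTRUE(msg)) return(msg)
      }
    }
    TRUE
  }
  msg <- check(object@steps)
  if (!isTRUE(msg)) return(msg)
  # safety interlock: no pressure pulse before puncture has been confirmed
  flat <- flattenMacroSteps(object@steps)
  acts2 <- vapply(flat, function(s) s$action, character(1))
  firstPulse <- match("pulse", acts2)
  firstPunct <- match("await_puncture", acts2)
  if (!is.na(firstPulse) && (is.na(firstPunct) || firstPunct > firstPulse))
    return("await_puncture must precede any pulse")
  TRUE
})

#' Per-larva outcome log of an injection session
#'
#' @slot records data frame with one row per detected larva: larva id,
#'   site, mode, outcome (success/failure/skipped), failure reason,
#'   survival flag and simulated-clock timestamps.
#' @slot traces list of per-larva action traces (data frames).
#' @exportClass SessionRecord
setClass("SessionRecord", representation(records = "data.frame", traces = "list"))

setValidity("SessionRecord", function(object) {
  need <- c("larva_id", "site", "mode", "outcome", "reason",
            "t_start", "t_end", "survived")
  if (!all(need %in% names(object@records)))
    return(paste("records must contain columns:", paste(need, collapse = ", ")))
  if (!all(object@records$outcome %in% c("success", "failure", "skipped")))
    return("outcome must be success, failure or skipped")
  if (any(object@records$t_end < object@records$t_start))
    return("timestamps must be monotone per larva")
  TRUE
})

#' Session summary statistics
#'
#' @slot nInjected number of larvae actually injected (not skipped).
#' @slot successRate percentage of injected larvae with a successful macro.
#' @slot larvaePerHour throughput on the simulated clock.
#' @slot survivalRate percentage of successes surviving the outcome model
#'   (an explicit placeholder; survival is biological, not computable).
#' @slot sdSuccessRate standard deviation across sessions (0 with
#'   \code{singleSession = TRUE} when only one session was summarized).
#' @slot singleSession flag: TRUE when the sd is a degenerate n = 1 value.
#' @exportClass SessionSummary
setClass("SessionSummary",
         representation(nInjected = "integer", successRate = "numeric",
                        larvaePerHour = "numeric", survivalRate = "numeric",
                        sdSuccessRate = "numeric", singleSession = "logical"))

setValidity("SessionSummary", function(object) {
  rates <- c(object@successRate, object@survivalRate)
  if (any(rates < 0 | rates > 100)) return("rates must lie within [0, 100]")
  if (object@nInjected > 0L && object@larvaePerHour <= 0)
    return("larvaePerHour must be positive when larvae were injected")
  TRUE
})

setMethod("show", "LabelMap", function(object) {
  d <- dim(object@raster)
  cat(sprintf("LabelMap: %d x %d pixels, %d classes\n",
              d[2], d[1], length(object@classes)))
  tab <- table(factor(object@classes[object@raster + 1L],
                      levels = object@classes))
  present <- tab[tab > 0]
  cat("  pixels per class:",
      paste(sprintf("%s=%d", names(present), present), collapse = ", "), "\n")
})

setMethod("show", "ProbabilityMap", function(object) {
  d <- dim(object@scores)
  cat(sprintf("ProbabilityMap: %d x %d pixels, %d classes (scores in [%.3g, %.3g])\n",
              d[2], d[1], d[3], min(object@scores), max(object@scores)))
})

setMethod("show", "FrameSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameSequence (%s): %d frames of %d x %d pixels\n",
              object@kind, d[3], d[2], d[1]))
})

setMethod("show", "SyntheticPlate", function(object) {
  d <- dim(object@image)
  cat(sprintf("SyntheticPlate: %d x %d pixels, %d larvae (seed %d)\n",
              d[2], d[1], length(object@larvae), object@seed))
})

setMethod("show", "SkewedFrame", function(object) {
  cat(sprintf("SkewedFrame: origin (%.2f, %.2f), u (%.2f, %.2f), v (%.2f, %.2f)\n",
              object@origin[1], object@origin[2], object@u[1], object@u[2],
              object@v[1], object@v[2]))
})

setMethod("show", "NeedlePose", function(object) {
  cat(sprintf("NeedlePose[%s]: tip (%.2f, %.2f), angle %.1f deg\n",
              object@site, object@tip[1], object@tip[2], object@angleDeg))
})

setMethod("show", "BloodFlowMap", function(object) {
  cat(sprintf("BloodFlowMap: %d x %d pixels from %d frames, max activity %.3f\n",
              ncol(object@activity), nrow(object@activity),
              object@nFramesUsed, max(object@activity)))
})

setMethod("show", "InjectionMacro", function(object) {
  cat(sprintf("InjectionMacro '%s': %d top-level steps (%d flattened)\n",
              object@name, length(object@steps),
              length(flattenMacroSteps(object@steps))))
})

setMethod("show", "SessionRecord", function(object) {
  tab <- table(object@records$outcome)
  cat(sprintf("SessionRecord: %d larvae (%s)\n", nrow(object@records),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "SessionSummary", function(object) {
  cat(sprintf("SessionSummary: %d injected, success %.1f%%, %.1f larvae/h, survival %.1f%%\n",
              object@nInjected, object@successRate, object@larvaePerHour,
              object@survivalRate))
})
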