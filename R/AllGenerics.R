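#' @include AllClasses.R
NULL

#' Accessors for pipeline data objects
#'
#' Small accessor generics so user code never reaches into slots.
#'
#' @param x an object from this package.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))
#' @rdname accessors
#' @export
setMethod("classNames", "LabelMap", function(x) x@classes)
#' @rdname accessors
#' @export
setMethod("classNames", "ProbabilityMap", function(x) x@classes)

#' @rdname accessors
#' @export
setGeneric("labelRaster", function(x) standardGeneric("labelRaster"))
#' @rdname accessors
#' @export
setMethod("labelRaster", "LabelMap", function(x) x@raster)

#' @rdname accessors
#' @export
setGeneric("scoreArray", function(x) standardGeneric("scoreArray"))
#' @rdname accessors
#' @export
setMethod("scoreArray", "ProbabilityMap", function(x) x@scores)

#' @rdname accessors
#' @export
setGeneric("frameArray", function(x) standardGeneric("frameArray"))
#' @rdname accessors
#' @export
setMethod("frameArray", "FrameSequence", function(x) x@frames)

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setMethod("nFrames", "FrameSequence", function(x) dim(x@frames)[3])

#' @rdname accessors
#' @export
setGeneric("plateImage", function(x) standardGeneric("plateImage"))
#' @rdname accessors
#' @export
setMethod("plateImage", "SyntheticPlate", function(x) x@image)

#' @rdname accessors
#' @export
setGeneric("plateTruth", function(x) standardGeneric("plateTruth"))
#' @rdname accessors
#' @export
setMethod("plateTruth", "SyntheticPlate", function(x) x@truth)

#' @rdname accessors
#' @export
setGeneric("plateLarvae", function(x) standardGeneric("plateLarvae"))
#' @rdname accessors
#' @export
setMethod("plateLarvae", "SyntheticPlate", function(x) x@larvae)

#' @rdname accessors
#' @export
setGeneric("regionMasks", function(x) standardGeneric("regionMasks"))
#' @rdname accessors
#' @export
setMethod("regionMasks", "SyntheticLarva", function(x) x@regionMasks)

#' @rdname accessors
#' @export
setGeneric("larvaLandmarks", function(x) standardGeneric("larvaLandmarks"))
#' @rdname accessors
#' @export
setMethod("larvaLandmarks", "SyntheticLarva", function(x) x@landmarks)

#' @rdname accessors
#' @export
setGeneric("activityMap", function(x) standardGeneric("activityMap"))
#' @rdname accessors
#' @export
setMethod("activityMap", "BloodFlowMap", function(x) x@activity)

#' @rdname accessors
#' @export
setGeneric("needleTip", function(x) standardGeneric("needleTip"))
#' @rdname accessors
#' @export
setMethod("needleTip", "NeedlePose", function(x) x@tip)

#' @rdname accessors
#' @export
setGeneric("needleAngle", function(x) standardGeneric("needleAngle"))
#' @rdname accessors
#' @export
setMethod("needleAngle", "NeedlePose", function(x) x@angleDeg)

#' @rdname accessors
#' @export
setGeneric("anchorPoints", function(x) standardGeneric("anchorPoints"))
#' @rdname accessors
#' @export
setMethod("anchorPoints", "AnchorPointSet", function(x) x@points)

#' @rdname accessors
#' @export
setGeneric("anchorDisplacements", function(x) standardGeneric("anchorDisplacements"))
#' @rdname accessors
#' @export
setMethod("anchorDisplacements", "AnchorPointSet", function(x) x@displacements)

#' @rdname accessors
#' @export
setGeneric("macroSteps", function(x) standardGeneric("macroSteps"))
#' @rdname accessors
#' @export
setMethod("macroSteps", "InjectionMacro", function(x) x@steps)

#' @rdname accessors
#' @export
setGeneric("sessionRecords", function(x) standardGeneric("sessionRecords"))
#' @rdname accessors
#' @export
setMethod("sessionRecords", "SessionRecord", function(x) x@records)

#' @rdname accessors
#' @export
setGeneric("sessionTraces", function(x) standardGeneric("sessionTraces"))
#' @rdname accessors
#' @export
setMethod("sessionTraces", "SessionRecord", function(x) x@traces)

#' Construct a LabelMap
#'
#' @param raster integer matrix of 0-based class indices (rows = y).
#' @param classes ordered character vector of class names; defaults to the
#'   pipeline's anatomy class list, see [anatomyClasses()].
#' @return a \linkS4class{LabelMap}.
#' @export
LabelMap <- function(raster, classes = anatomyClasses()) {
  storage.mode(raster) <- "integer"
  new("LabelMap", classes = classes, raster = raster)
}

#' Construct a ProbabilityMap
#'
#' @param scores H x W x N numeric array of per-class scores.
#' @param classes ordered character vector of N class names.
#' @return a \linkS4class{ProbabilityMap}.
#' @export
ProbabilityMap <- function(scores, classes = anatomyClasses()) {
  new("ProbabilityMap", classes = classes, scores = scores)
}

#' Construct a TilingScheme
#'
#' @param tileSize tile edge length in pixels (default 304).
#' @param overlap overlap between neighbouring tiles in pixels (default 50).
#' @return a \linkS4class{TilingScheme}.
#' @export
TilingScheme <- function(tileSize = 304L, overlap = 50L) {
  new("TilingScheme", tileSize = as.integer(tileSize),
      overlap = as.integer(overlap))
}

#' Construct a FrameSequence
#'
#' @param frames H x W x T numeric array, or a list of equally sized
#'   matrices that is stacked along the third dimension.
#' @param kind \code{"time"} for videos, \code{"z"} for focal stacks.
#' @return a \linkS4class{FrameSequence}.
#' @export
FrameSequence <- function(frames, kind = c("time", "z")) {
  kind <- match.arg(kind)
  if (is.list(frames)) {
    d <- dim(frames[[1]])
    if (!all(vapply(frames, function(f) identical(dim(f), d), TRUE)))
      stop("all frames must have identical dimensions")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(d, length(frames)))
  }
  new("FrameSequence", frames = frames, kind = kind)
}

#' Construct a SkewedFrame directly from basis vectors
#'
#' Most users should call [buildSkewedFrame()] on a \linkS4class{LandmarkSet}.
#'
#' @param origin,u,v plate points / vectors, each c(x, y).
#' @return a \linkS4class{SkewedFrame}.
#' @export
SkewedFrame <- function(origin, u, v) {
  new("SkewedFrame", origin = as.numeric(origin), u = as.numeric(u),
      v = as.numeric(v))
}

#' Construct a LandmarkSet
#'
#' @param eyes,yolk,swimBladder plate points c(x, y).
#' @return a \linkS4class{LandmarkSet}.
#' @export
LandmarkSet <- function(eyes, yolk, swimBladder) {
  new("LandmarkSet", eyes = as.numeric(eyes), yolk = as.numeric(yolk),
      swimBladder = as.numeric(swimBladder))
}

#' Construct a NeedlePose
#'
#' @param tip plate point c(x, y).
#' @param angleDeg needle yaw in degrees (normalized to [0, 360)).
#' @param site injection-site label.
#' @return a \linkS4class{NeedlePose}.
#' @export
NeedlePose <- function(tip, angleDeg, site = "unspecified") {
  new("NeedlePose", tip = as.numeric(tip),
      angleDeg = normalizeAngle(angleDeg), site = site)
}

#' Construct an InjectionMacro
#'
#' @param name macro name.
#' @param steps list of steps; each a named list with an \code{action}
#'   element (see \linkS4class{InjectionMacro} for the action vocabulary).
#' @return an \linkS4class{InjectionMacro}.
#' @export
InjectionMacro <- function(name, steps) {
  new("InjectionMacro", name = name, steps = steps)
}
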