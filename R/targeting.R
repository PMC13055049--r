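#' @include segmentation.R
NULL

#' Landmark centroids from a segmented larva
#'
#' Computes the arithmetic centroids of the eye (union of both eyes),
#' yolk and swim-bladder class masks — the three anatomical landmarks
#' from which the larva's coordinate frame is constructed.
#'
#' @param labels a \linkS4class{LabelMap} of one larva.
#' @return a \linkS4class{LandmarkSet}.
#' @export
landmarkCentroids <- function(labels) {
  r <- labelRaster(labels)
  classes <- classNames(labels)
  centroidOf <- function(cls) {
    idx <- match(cls, classes)
    if (is.na(idx)) stop(sprintf("class '%s' not in the class list", cls))
    mask <- r == idx - 1L
    if (!any(mask))
      stop(sprintf("missing landmark: class '%s' is absent from the segmentation", cls))
    maskCentroid(mask)
  }
  LandmarkSet(eyes = centroidOf("eye"), yolk = centroidOf("yolk"),
              swimBladder = centroidOf("swim_bladder"))
}

#' Build the skewed larva coordinate frame
#'
#' Constructs the non-orthogonal frame in which user-defined injection
#' coordinates are expressed: origin at the eyes centroid, first basis
#' vector toward the yolk centroid, second toward the swim-bladder
#' centroid. Near-collinear landmarks (normalized cross product below
#' 1e-3) are rejected as degenerate.
#'
#' @param lm a \linkS4class{LandmarkSet}.
#' @return a \linkS4class{SkewedFrame}.
#' @export
buildSkewedFrame <- function(lm) {
  u <- lm@yolk - lm@eyes
  v <- lm@swimBladder - lm@eyes
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0 ||
      abs(u[1] * v[2] - u[2] * v[1]) / (nu * nv) < 1e-3)
    stop("degenerate frame: landmarks are collinear")
  SkewedFrame(origin = lm@eyes, u = u, v = v)
}

#' Map site coordinates to plate pixels and back
#'
#' \code{toPlate} evaluates the affine map origin + a*u + b*v;
#' \code{fromPlate} is its exact algebraic inverse. The pair is an exact
#' round trip on any non-degenerate frame.
#'
#' @param frame a \linkS4class{SkewedFrame}.
#' @param ab site coordinates c(a, b) (or an n x 2 matrix).
#' @param xy plate point c(x, y) (or an n x 2 matrix).
#' @return the mapped point(s), same shape as the input.
#' @export
toPlate <- function(frame, ab) {
  if (is.matrix(ab))
    return(t(apply(ab, 1, function(p) toPlate(frame, p))))
  frame@origin + ab[1] * frame@u + ab[2] * frame@v
}

#' @rdname toPlate
#' @export
fromPlate <- function(frame, xy) {
  if (is.matrix(xy))
    return(t(apply(xy, 1, function(p) fromPlate(frame, p))))
  M <- cbind(frame@u, frame@v)
  as.numeric(solve(M, xy - frame@origin))
}

#' Orientation-aware needle angle
#'
#' Larvae are placed on the plate in random orientations; the needle is
#' rotated to a configured angle relative to each larva's own heading.
#' The heading is the direction of the eyes-to-swim-bladder axis.
#'
#' @param lm a \linkS4class{LandmarkSet}.
#' @param configuredAngleDeg needle angle offset relative to the heading.
#' @return list with \code{headingDeg} and \code{angleDeg} (both
#'   normalized to [0, 360)).
#' @export
orientationAndAngle <- function(lm, configuredAngleDeg = 0) {
  d <- lm@swimBladder - lm@eyes
  if (sqrt(sum(d^2)) < 1e-9) stop("degenerate landmarks: eyes and swim bladder coincide")
  heading <- normalizeAngle(atan2(d[2], d[1]) * 180 / pi)
  list(headingDeg = heading,
       angleDeg = normalizeAngle(heading + configuredAngleDeg))
}

# Snap a plate point to the nearest TRUE pixel of a mask; returns c(x, y).
nearestMaskPixel <- function(mask, xy) {
  idx <- which(mask, arr.ind = TRUE)
  px <- idx[, 2] - 1; py <- idx[, 1] - 1
  i <- which.min((px - xy[1])^2 + (py - xy[2])^2)
  c(px[i], py[i])
}

#' Needle target on the duct of Cuvier
#'
#' Default behaviour ("duct of Cuvier" site) targets the middle of the
#' DoC: the centroid of the largest DoC component, snapped to the nearest
#' DoC pixel. With a user-chosen point ("duct of Cuvier (choose point)"
#' site) the point, expressed in the skewed frame, is mapped to the plate
#' and projected onto the nearest DoC pixel.
#'
#' @param flowLabels \linkS4class{LabelMap} derived from the blood-flow
#'   overlay segmentation; must contain the duct_of_cuvier class.
#' @param frame the larva's \linkS4class{SkewedFrame}.
#' @param userPoint optional site coordinates c(a, b) in the skewed frame.
#' @param angleOffsetDeg needle angle relative to the larva heading.
#' @return a \linkS4class{NeedlePose}.
#' @export
docTarget <- function(flowLabels, frame, userPoint = NULL,
                      angleOffsetDeg = 0) {
  comp <- largestComponent(flowLabels, "duct_of_cuvier")
  if (comp$absent)
    stop("site not found: no duct_of_cuvier component in the segmentation")
  target <- if (is.null(userPoint)) {
    maskCentroid(comp$mask)
  } else {
    toPlate(frame, userPoint)
  }
  tip <- nearestMaskPixel(comp$mask, target)
  heading <- normalizeAngle(atan2(frame@v[2], frame@v[1]) * 180 / pi)
  site <- if (is.null(userPoint)) "doc_mid" else "doc_choose"
  NeedlePose(tip, normalizeAngle(heading + angleOffsetDeg), site)
}

#' Needle pose for hindbrain-ventricle injections
#'
#' The hindbrain macro consumes two annotated points: the needle starting
#' point and a second point giving the needle direction.
#'
#' @param startPoint plate point c(x, y): where the needle starts.
#' @param directionPoint plate point the needle is aimed at.
#' @return a \linkS4class{NeedlePose} with site "hindbrain".
#' @export
hindbrainPose <- function(startPoint, directionPoint) {
  d <- directionPoint - startPoint
  if (sqrt(sum(d^2)) < 1e-9)
    stop("start and direction points coincide")
  NeedlePose(startPoint, normalizeAngle(atan2(d[2], d[1]) * 180 / pi),
             "hindbrain")
}

#' Needle pose for perivitelline-space injections
#'
#' Positions the needle tip on the upper border of the PVS — the
#' boundary pixels on the positive v-axis side of the larva's own frame,
#' so the rule is invariant to how the larva lies on the plate — at an
#' entry angle of 30-60 degrees relative to the larva heading.
#'
#' @param labels \linkS4class{LabelMap} containing the
#'   perivitelline_space class.
#' @param frame the larva's \linkS4class{SkewedFrame}.
#' @param angleDeg entry angle in degrees; must lie within [30, 60].
#' @param entryAb preferred entry location in skewed coordinates; the
#'   admissible boundary pixel closest to it is chosen.
#' @return a \linkS4class{NeedlePose} with site "pvs".
#' @export
pvsPose <- function(labels, frame, angleDeg = 45, entryAb = c(0.5, 0.5)) {
  if (angleDeg < 30 || angleDeg > 60)
    stop("PVS entry angle must lie within [30, 60] degrees")
  comp <- largestComponent(labels, "perivitelline_space")
  if (comp$absent)
    stop("site not found: no perivitelline_space component in the segmentation")
  mask <- comp$mask
  # boundary = mask pixels with at least one 4-neighbour outside the mask
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  inner <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  boundary <- mask & !inner
  idx <- which(boundary, arr.ind = TRUE)
  pts <- cbind(idx[, 2] - 1, idx[, 1] - 1)
  ab <- fromPlate(frame, pts)
  upper <- ab[, 2] >= stats::median(ab[, 2])
  pts <- pts[upper, , drop = FALSE]
  ab <- ab[upper, , drop = FALSE]
  i <- which.min((ab[, 1] - entryAb[1])^2 + (ab[, 2] - entryAb[2])^2)
  heading <- normalizeAngle(atan2(frame@v[2], frame@v[1]) * 180 / pi)
  NeedlePose(pts[i, ], normalizeAngle(heading + angleDeg), "pvs")
}
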