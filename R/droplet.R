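#' @include puncture.R
NULL

#' Measure the injection droplet in mineral oil
#'
#' Segments the darkest blob in a droplet-in-oil snapshot, fits its
#' equivalent-area circle and converts to physical units. Blobs that are
#' not round enough (moment-based circularity below the floor) are
#' rejected as debris: droplets expelled into oil are near-spherical.
#' Circularity is defined from the second moments as
#' area / (2 * pi * Rg^2), where Rg is the radius of gyration about the
#' centroid; it equals 1 for an ideal disk and 2ab/(a^2+b^2) for an
#' ellipse with semi-axes a, b.
#'
#' @param image grayscale snapshot (dark droplet on bright oil).
#' @param scaleUmPerPx optical scale in micrometres per pixel.
#' @param circularityFloor minimum accepted circularity (default 0.8).
#' @param ambiguityRatio a second blob at least this fraction of the
#'   largest blob's area triggers an ambiguity error.
#' @return a \linkS4class{DropletMeasurement}.
#' @export
measureDroplet <- function(image, scaleUmPerPx, circularityFloor = 0.8,
                           ambiguityRatio = 0.5) {
  if (scaleUmPerPx <= 0) stop("scale must be positive")
  lo <- stats::quantile(image, 0.001); hi <- stats::quantile(image, 0.999)
  if (hi - lo < 0.2)
    stop("droplet not found: no dark blob in the image")
  thr <- (lo + hi) / 2
  mask <- image < thr
  comp <- labelComponents(mask)
  sizes <- tabulate(comp[comp > 0L])
  sizes <- sizes[sizes > 4L]  # ignore speckle
  if (length(sizes) == 0L)
    stop("droplet not found: no dark blob in the image")
  ord <- order(tabulate(comp[comp > 0L]), decreasing = TRUE)
  areas <- tabulate(comp[comp > 0L])[ord]
  if (length(areas) > 1L && areas[2] >= ambiguityRatio * areas[1])
    stop(sprintf("ambiguous droplet detection: candidate areas %s px",
                 paste(areas[areas >= ambiguityRatio * areas[1]],
                       collapse = ", ")))
  blob <- comp == ord[1]
  idx <- which(blob, arr.ind = TRUE)
  px <- idx[, 2] - 1; py <- idx[, 1] - 1
  area <- length(px)
  cx <- mean(px); cy <- mean(py)
  rg2 <- mean((px - cx)^2 + (py - cy)^2) + 1 / 6  # pixel-area correction
  circ <- min(area / (2 * pi * rg2), 1)
  if (circ < circularityFloor)
    stop(sprintf("droplet rejected: circularity %.2f below floor %.2f (elongated blob, likely debris)",
                 circ, circularityFloor))
  # sub-pixel area: anti-aliased edge pixels contribute their fractional
  # coverage (bg - I) / (bg - fg), summed over the blob neighbourhood
  x0 <- max(0L, min(px) - 3L); x1 <- min(ncol(image) - 1L, max(px) + 3L)
  y0 <- max(0L, min(py) - 3L); y1 <- min(nrow(image) - 1L, max(py) + 3L)
  sub <- image[(y0 + 1L):(y1 + 1L), (x0 + 1L):(x1 + 1L)]
  bg <- stats::median(image[!blob])   # robust intensity anchors
  fg <- stats::median(image[blob])
  areaSub <- sum(clampValues((bg - sub) / (bg - fg)))
  dPx <- 2 * sqrt(areaSub / pi)
  dUm <- dPx * scaleUmPerPx
  new("DropletMeasurement", diameterPx = dPx, diameterUm = dUm,
      volumeNl = dropletVolume(dUm), circularity = circ,
      center = c(cx, cy))
}

#' Spherical droplet volume from its diameter
#'
#' @param diameterUm droplet diameter in micrometres (>= 0).
#' @return volume (pi/6) d^3 in nanolitres (1 um^3 = 1e-6 nL).
#' @export
dropletVolume <- function(diameterUm) {
  if (any(diameterUm < 0)) stop("diameter must be non-negative")
  (pi / 6) * diameterUm^3 * 1e-6
}

#' Proportional injection-pressure recommendation
#'
#' First-order pressure-volume model: the delivered volume is taken as
#' proportional to pressure, so the recommended new pressure is
#' current * target / measured, clamped to a safe range. Iterating the
#' rule converges when measurement noise is multiplicative and bounded.
#'
#' @param measuredNl measured droplet volume in nL (> 0; zero signals a
#'   blocked needle and raises an error).
#' @param targetNl desired volume in nL.
#' @param currentPressure current pressure setting.
#' @param pressureRange safe c(min, max) clamp.
#' @return recommended pressure.
#' @export
recommendPressure <- function(measuredNl, targetNl, currentPressure,
                              pressureRange = c(50, 1000)) {
  if (targetNl <= 0 || currentPressure <= 0)
    stop("target volume and current pressure must be positive")
  if (measuredNl <= 0)
    stop("measured volume is zero: needle may be blocked")
  clampValues(currentPressure * targetNl / measuredNl,
              pressureRange[1], pressureRange[2])
}
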