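#' @include io.R
NULL

#' End-to-end pipeline stages (the command-line entry points)
#'
#' These functions are the programmatic bodies of the shipped CLI script
#' (\code{system.file("scripts", "larvainject.R", package =
#' "larvaInject")}): plate simulation, segmentation, blood-flow mapping
#' and session execution, all file-to-file and fully seeded.
#'
#' @param seed integer seed.
#' @param outDir output directory (created if missing).
#' @param nLarvae number of larvae on the simulated plate.
#' @param imageSize plate size c(width, height) in pixels.
#' @return list of written file paths, invisibly where noted.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
pipelineSimulatePlate <- function(seed, outDir, nLarvae = 20L,
                                  imageSize = c(1024L, 1024L)) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  plate <- generatePlate(nLarvae = nLarvae, imageSize = imageSize,
                         seed = seed)
  paths <- list(
    image = file.path(outDir, "plate.png"),
    truth = file.path(outDir, "truth.png"),
    landmarks = file.path(outDir, "landmarks.yaml"))
  writeImagePNG(plateImage(plate), paths$image)
  writeLabelMapPNG(plateTruth(plate), paths$truth)
  writeLandmarksYaml(plate, paths$landmarks)
  invisible(c(paths, list(plate = plate)))
}

#' @rdname pipeline
#' @param plateImagePath input plate PNG.
#' @param outPath output label-map PNG.
#' @param tileSize,overlapPx tiling layout (defaults 304 / 50).
#' @param tta apply six-transform consensus voting.
#' @export
pipelineSegment <- function(plateImagePath, outPath, tileSize = 304L,
                            overlapPx = 50L, tta = FALSE) {
  image <- readImagePNG(plateImagePath)
  labels <- segmentImage(image, templateSegmenter(),
                         TilingScheme(tileSize, overlapPx), tta = tta)
  writeLabelMapPNG(labels, outPath)
  invisible(outPath)
}

#' @rdname pipeline
#' @param framesPath multi-page TIFF of blood-flow frames.
#' @param mapPath,overlayPath output activity map / overlay PNGs.
#' @export
pipelineBloodflow <- function(framesPath, mapPath, overlayPath = NULL) {
  seq <- readFrameSequenceTIFF(framesPath)
  map <- bloodFlowMap(seq)
  writeImagePNG(activityMap(map), mapPath)
  if (!is.null(overlayPath)) {
    fr <- frameArray(seq)
    rgb <- overlayFlow(map, fr[, , dim(fr)[3]])
    png::writePNG(rgb, overlayPath)
  }
  invisible(mapPath)
}

#' @rdname pipeline
#' @param platePath plate image PNG.
#' @param sessionCsv,summaryJson output paths.
#' @param site injection site label.
#' @param mode "automated" or "semi_automated".
#' @param macro an \linkS4class{InjectionMacro} or a YAML macro path.
#' @export
pipelineRunSession <- function(platePath, sessionCsv, summaryJson,
                               site = "doc_mid",
                               mode = "automated",
                               macro = defaultMacro("doc"), seed = 1L) {
  if (is.character(macro)) macro <- macroFromYaml(macro)
  image <- readImagePNG(platePath)
  record <- runSession(image, macro, mode = mode, seed = seed, site = site)
  sessionToCsv(record, sessionCsv)
  summaryToJson(summarizeSession(record), summaryJson)
  invisible(list(session = sessionCsv, summary = summaryJson))
}

#' Run the whole pipeline under one seed
#'
#' simulate-plate, segment, run-session and summarize in sequence,
#' writing every artifact into \code{outDir}. The run is a pure function
#' of the seed: repeating it writes byte-identical files.
#'
#' @rdname pipeline
#' @export
runPipeline <- function(seed, outDir, nLarvae = 12L,
                        imageSize = c(700L, 700L)) {
  sim <- pipelineSimulatePlate(seed, outDir, nLarvae = nLarvae,
                               imageSize = imageSize)
  labelsPath <- file.path(outDir, "labels.png")
  pipelineSegment(sim$image, labelsPath)
  out <- pipelineRunSession(sim$image,
                            file.path(outDir, "session.csv"),
                            file.path(outDir, "summary.json"),
                            seed = seed)
  invisible(list(image = sim$image, truth = sim$truth,
                 landmarks = sim$landmarks, labels = labelsPath,
                 session = out$session, summary = out$summary))
}
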