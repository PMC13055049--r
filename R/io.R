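#' @include session.R
NULL

#' Write and read grayscale images
#'
#' Images are exchanged as 8-bit PNG or 16-bit TIFF; in memory they are
#' numeric matrices in [0, 1].
#'
#' @param image numeric matrix in [0, 1].
#' @param path file path.
#' @return readers return the matrix; writers return the path invisibly.
#' @export
writeImagePNG <- function(image, path) {
  png::writePNG(clampValues(image), path)
  invisible(path)
}

#' @rdname writeImagePNG
#' @export
readImagePNG <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' @rdname writeImagePNG
#' @export
writeImageTIFF <- function(image, path) {
  tiff::writeTIFF(clampValues(image), path, bits.per.sample = 16L)
  invisible(path)
}

#' Write / read a label map as an indexed 8-bit PNG
#'
#' Class indices are stored directly as gray values 0..N-1 (documented in
#' the class palette, see [writeClassPalette()]).
#'
#' @param labels a \linkS4class{LabelMap}.
#' @param path file path.
#' @param classes class list for reading back.
#' @return the \linkS4class{LabelMap} (readers) or the path (writers,
#'   invisibly).
#' @export
writeLabelMapPNG <- function(labels, path) {
  png::writePNG(labelRaster(labels) / 255, path)
  invisible(path)
}

#' @rdname writeLabelMapPNG
#' @export
readLabelMapPNG <- function(path, classes = anatomyClasses()) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  LabelMap(matrix(as.integer(round(img * 255)), nrow(img), ncol(img)),
           classes)
}

#' Write the class-integer palette as YAML
#'
#' @param path file path.
#' @param classes class list.
#' @return the path, invisibly.
#' @export
writeClassPalette <- function(path, classes = anatomyClasses()) {
  lv <- paintLevels()
  yaml::write_yaml(list(classes = as.list(stats::setNames(
    seq_along(classes) - 1L, classes)),
    paint_levels = as.list(lv)), path)
  invisible(path)
}

#' Write / read a frame sequence as multi-page TIFF
#'
#' @param seq a \linkS4class{FrameSequence}.
#' @param path file path.
#' @param kind sequence kind for reading back.
#' @return the \linkS4class{FrameSequence} (reader) or the path (writer).
#' @export
writeFrameSequenceTIFF <- function(seq, path) {
  fr <- frameArray(seq)
  pages <- lapply(seq_len(dim(fr)[3]), function(i) clampValues(fr[, , i]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeFrameSequenceTIFF
#' @export
readFrameSequenceTIFF <- function(path, kind = c("time", "z")) {
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  FrameSequence(pages, kind = match.arg(kind))
}

#' Read a frame sequence from a directory of numbered PNGs
#'
#' @param dir directory containing frames as PNG files, ordered by name.
#' @param kind sequence kind.
#' @return a \linkS4class{FrameSequence}.
#' @export
readFrameSequenceDir <- function(dir, kind = c("time", "z")) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) < 2L) stop("need at least 2 frames")
  FrameSequence(lapply(files, readImagePNG), kind = match.arg(kind))
}

#' Ground-truth sidecar files
#'
#' Events and landmarks of synthetic fixtures travel as YAML sidecars so
#' downstream checks never depend on binary formats.
#'
#' @param events list of ground-truth event lists (kind, index).
#' @param path file path.
#' @return read side returns the structure; write side the path.
#' @export
writeEventsYaml <- function(events, path) {
  yaml::write_yaml(events, path)
  invisible(path)
}

#' @rdname writeEventsYaml
#' @export
readEventsYaml <- function(path) yaml::read_yaml(path)

#' Write plate ground truth landmarks as a YAML sidecar
#'
#' @param plate a \linkS4class{SyntheticPlate}.
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeLandmarksYaml <- function(plate, path) {
  ll <- lapply(plateLarvae(plate), function(lar) {
    list(position = as.list(stats::setNames(lar@position, c("x", "y"))),
         heading_deg = lar@headingDeg,
         landmarks = lapply(lar@landmarks, function(p)
           list(x = p[1], y = p[2])))
  })
  yaml::write_yaml(list(seed = plate@seed, larvae = ll), path)
  invisible(path)
}

#' Export needle poses as CSV
#'
#' @param poses list of \linkS4class{NeedlePose} objects, named or
#'   indexed by larva.
#' @param path file path.
#' @return the path, invisibly.
#' @export
posesToCsv <- function(poses, path) {
  df <- data.frame(
    larva_id = seq_along(poses),
    x = vapply(poses, function(p) p@tip[1], numeric(1)),
    y = vapply(poses, function(p) p@tip[2], numeric(1)),
    angle_deg = vapply(poses, function(p) p@angleDeg, numeric(1)),
    site = vapply(poses, function(p) p@site, character(1)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a session record as CSV and a summary as JSON
#'
#' @param record a \linkS4class{SessionRecord}.
#' @param summary a \linkS4class{SessionSummary}.
#' @param path file path.
#' @return the path, invisibly.
#' @export
sessionToCsv <- function(record, path) {
  utils::write.csv(sessionRecords(record), path, row.names = FALSE)
  invisible(path)
}

#' @rdname sessionToCsv
#' @export
summaryToJson <- function(summary, path) {
  jsonlite::write_json(list(
    n_injected = summary@nInjected,
    success_rate = summary@successRate,
    larvae_per_hour = summary@larvaePerHour,
    survival_rate = summary@survivalRate,
    sd_success_rate = summary@sdSuccessRate,
    single_session = summary@singleSession), path, auto_unbox = TRUE,
    digits = NA)
  invisible(path)
}
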