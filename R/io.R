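#' Read and write eye traces as delimited text
#'
#' Two-column text files (\code{time_s}, \code{position_deg}) with a
#' header, one file per eye.
#'
#' @param trace an [EyeTrace-class].
#' @param path file path.
#' @param eye eye label to attach on read.
#' @return \code{readEyeTrace} returns an [EyeTrace-class];
#'   \code{writeEyeTrace} returns \code{path} invisibly.
#' @export
writeEyeTrace <- function(trace, path) {
  stopifnot(is(trace, "EyeTrace"))
  utils::write.csv(data.frame(time_s = traceTime(trace),
                              position_deg = tracePosition(trace)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEyeTrace
#' @export
readEyeTrace <- function(path, eye = "left") {
  d <- utils::read.csv(path)
  EyeTrace(d$time_s, d$position_deg, eye)
}

#' Write and read saccade events as CSV
#'
#' @param events saccade data frame from [detectSaccades()].
#' @param path file path.
#' @return The data frame (read) or \code{path} invisibly (write).
#' @export
writeSaccadeEvents <- function(events, path) {
  utils::write.csv(data.frame(onset_s = events$onset,
                              direction = events$direction,
                              amplitude_deg = events$amplitude),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSaccadeEvents
#' @export
readSaccadeEvents <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(onset = d$onset_s, direction = d$direction,
             amplitude = d$amplitude_deg, stringsAsFactors = FALSE)
}

#' Write and read behavioural ground truth as JSON
#'
#' Round-trips the generator ground truth (saccade times, directions,
#' amplitudes, fixation table) without loss.
#'
#' @param truth ground-truth list from [genEyeTrace()].
#' @param path file path.
#' @return The truth list (read) or \code{path} invisibly (write).
#' @export
writeGroundTruth <- function(truth, path) {
  payload <- list(saccadeTimes = truth$saccadeTimes,
                  directions = truth$directions,
                  amplitudes = truth$amplitudes,
                  fixations = truth$fixations)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  d$directions <- as.integer(d$directions)
  d$fixations <- as.data.frame(d$fixations)
  d
}

#' Write and read a frame stack as multipage TIFF
#'
#' Frames are rescaled to [0, 1] jointly (TIFF stores normalised
#' intensities); the scale is returned on read via the
#' \code{"range"} attribute.
#'
#' @param frames list of matrices from [genFrames()].
#' @param path file path.
#' @return List of matrices (read) or \code{path} invisibly (write).
#' @export
writeFrameStack <- function(frames, path) {
  rng <- range(unlist(lapply(frames, range)))
  span <- diff(rng)
  if (span == 0) span <- 1
  norm <- lapply(frames, function(f) (f - rng[1]) / span)
  tiff::writeTIFF(norm, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname writeFrameStack
#' @export
readFrameStack <- function(path) {
  fr <- tiff::readTIFF(path, all = TRUE)
  lapply(fr, function(f) if (length(dim(f)) == 3) f[, , 1] else f)
}
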