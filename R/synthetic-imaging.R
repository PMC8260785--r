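#' Generate a translated frame stack
#'
#' Builds a stack of frames, each a circularly translated copy of a base
#' image plus optional Gaussian noise. Selected frames are replaced by a
#' structured distortion (pixel shuffling) emulating frames corrupted by
#' animal movement, which destroys their correlation with the reference.
#'
#' @param baseImage numeric matrix.
#' @param shifts n x 2 integer matrix of per-frame (row, col) shifts.
#' @param corruptFrames integer indices of frames to corrupt.
#' @param noiseSD SD of additive Gaussian noise.
#' @param seed integer RNG seed.
#' @return A list of frame matrices.
#' @export
genFrames <- function(baseImage, shifts, corruptFrames = integer(),
                      noiseSD = 0, seed = 1L) {
  stopifnot(is.matrix(baseImage))
  shifts <- matrix(as.integer(round(shifts)), ncol = 2)
  if (any(!is.finite(shifts)))
    stop("shifts must be finite")
  if (any(abs(shifts[, 1]) > nrow(baseImage) / 2) ||
      any(abs(shifts[, 2]) > ncol(baseImage) / 2))
    stop("shift larger than half the frame")
  set.seed(as.integer(seed))
  lapply(seq_len(nrow(shifts)), function(k) {
    if (k %in% corruptFrames) {
      fr <- matrix(sample(as.vector(baseImage)), nrow(baseImage))
    } else {
      fr <- .circShift(baseImage, shifts[k, ])
    }
    if (noiseSD > 0)
      fr <- fr + matrix(stats::rnorm(length(fr), 0, noiseSD),
                        nrow(fr))
    fr
  })
}

#' Generate a synthetic time-averaged intensity image
#'
#' Places \code{nNuclei} bright, disk-shaped (Gaussian-profile) nuclei at
#' random positions with a minimum pairwise separation, plus Gaussian
#' background noise. Mimics a time-averaged two-photon image of
#' nuclear-localised indicator expression.
#'
#' @param nNuclei number of nuclei.
#' @param dim image dimensions (rows, cols).
#' @param radiusPx nominal nucleus radius in pixels.
#' @param minSeparationPx minimum centre-to-centre distance.
#' @param noiseSD background noise SD (nucleus peak is 1).
#' @param seed integer RNG seed.
#' @param maxTries placement attempts before giving up.
#' @return A list with \code{image} (matrix) and \code{centers}
#'   (n x 2 matrix of row/col centres).
#' @export
genIntensityImage <- function(nNuclei, dim = c(96, 96), radiusPx = 4,
                              minSeparationPx = 12, noiseSD = 0.02,
                              seed = 1L, maxTries = 2000) {
  set.seed(as.integer(seed))
  margin <- radiusPx + 2
  if (nNuclei > 0 && any(dim - 2 * margin < 1))
    stop("nuclei do not fit in the frame")
  centers <- matrix(numeric(0), ncol = 2)
  tries <- 0
  while (nrow(centers) < nNuclei) {
    cand <- c(stats::runif(1, margin, dim[1] - margin),
              stats::runif(1, margin, dim[2] - margin))
    ok <- !nrow(centers) ||
      all(sqrt(rowSums(sweep(centers, 2, cand)^2)) >= minSeparationPx)
    if (ok) centers <- rbind(centers, cand)
    tries <- tries + 1
    if (tries > maxTries)
      stop("could not place nuclei at the requested separation")
  }
  img <- matrix(0, dim[1], dim[2])
  if (nNuclei > 0) {
    rows <- matrix(seq_len(dim[1]), dim[1], dim[2])
    cols <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
    sig <- radiusPx / 1.5
    for (k in seq_len(nNuclei)) {
      d2 <- (rows - centers[k, 1])^2 + (cols - centers[k, 2])^2
      img <- img + exp(-d2 / (2 * sig^2))
    }
  }
  if (noiseSD > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, noiseSD), dim[1])
  img <- pmax(img, 0)
  dimnames(centers) <- NULL
  list(image = img, centers = centers)
}
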