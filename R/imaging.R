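#' Register a frame to a reference by cross-correlation
#'
#' Estimates the integer translation between a frame and a reference
#' image as the argmax of their 2-D circular cross-correlation, computed
#' in Fourier space after removing each image's mean. Returns the
#' estimated displacement of the frame relative to the reference, the
#' correction that aligns it, a normalised registration error
#' \code{sqrt(1 - peak normalised cross-correlation)}, and the corrected
#' frame.
#'
#' @param frame,reference numeric matrices of equal size.
#' @return A list with \code{shift} (row/col displacement of the frame),
#'   \code{correction} (\code{-shift}), \code{error} and
#'   \code{registered} (the frame translated by \code{correction}).
#'   A zero-variance frame gets \code{error = 1} and zero shift.
#' @export
registerFrame <- function(frame, reference) {
  stopifnot(is.matrix(frame), is.matrix(reference),
            all(dim(frame) == dim(reference)))
  f <- frame - mean(frame)
  r <- reference - mean(reference)
  nf <- sqrt(sum(f^2)); nr <- sqrt(sum(r^2))
  if (nf == 0 || nr == 0)
    return(list(shift = c(0L, 0L), correction = c(0L, 0L), error = 1,
                registered = frame))
  cc <- Re(stats::fft(stats::fft(f) * Conj(stats::fft(r)),
                      inverse = TRUE)) / length(f)
  peakIdx <- which.max(cc)
  pi1 <- (peakIdx - 1) %% nrow(cc)
  pj1 <- (peakIdx - 1) %/% nrow(cc)
  # wrap to signed shifts
  sh <- c(if (pi1 > nrow(cc) / 2) pi1 - nrow(cc) else pi1,
          if (pj1 > ncol(cc) / 2) pj1 - ncol(cc) else pj1)
  peak <- max(cc) / (nf * nr)
  err <- sqrt(max(0, 1 - min(1, peak)^2))
  list(shift = as.integer(sh), correction = as.integer(-sh),
       error = err, registered = .circShift(frame, -sh))
}

#' Flag frames corrupted by animal movement
#'
#' A frame is flagged when its registration error exceeds the median
#' error plus five times the raw median absolute deviation (no
#' consistency factor) of the errors across frames. Flagged frames'
#' pixels are treated as missing downstream.
#'
#' @param errors numeric per-frame registration errors.
#' @return Logical mask, TRUE for corrupted frames.
#' @export
flagCorruptedFrames <- function(errors) {
  stopifnot(length(errors) >= 2)
  med <- stats::median(errors)
  madRaw <- stats::mad(errors, constant = 1)
  errors > med + 5 * madRaw
}

# regional maxima of a grayscale image: connected plateaus of equal
# intensity whose 8-connected external boundary is strictly lower
.regionalMaxima <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- img
  nbmax <- matrix(-Inf, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nbmax <- pmax(nbmax, pad[2:(nr + 1) + di, 2:(nc + 1) + dj])
  }
  cand <- img >= nbmax  # local (weak) maxima, keeps plateaus
  lab <- EBImage::bwlabel(EBImage::Image(cand * 1))
  lab <- matrix(as.integer(lab), nr, nc)
  keep <- integer(0)
  for (l in seq_len(max(lab))) {
    px <- which(lab == l, arr.ind = TRUE)
    val <- img[px[1, 1], px[1, 2]]
    # plateau must be one intensity; boundary strictly lower
    if (any(abs(img[px] - val) > 0)) next
    ok <- TRUE
    for (k in seq_len(nrow(px))) {
      i <- px[k, 1]; j <- px[k, 2]
      nb <- pad[(i:(i + 2)), (j:(j + 2))]
      inPlateau <- matrix(FALSE, 3, 3)
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
          inPlateau[di + 2, dj + 2] <- lab[ii, jj] == l
      }
      if (any(nb[!inPlateau] >= val & is.finite(nb[!inPlateau]))) {
        ok <- FALSE
        break
      }
    }
    if (ok) keep <- c(keep, l)
  }
  list(labels = lab, maxima = keep)
}

#' Detect cell nuclei in a time-averaged intensity image
#'
#' Performs a morphological opening with a disk-shaped structuring
#' element, finds regional maxima (connected equal-intensity plateaus
#' whose external boundary pixels are all lower), takes one detection per
#' plateau at its centre of mass, and discards regions whose plateau area
#' exceeds \code{maxAreaPx2} (larger than a cell nucleus). Plateaus
#' dimmer than \code{minRelIntensity} times the maximum of the opened
#' image are treated as background, which keeps the detection count
#' invariant to global intensity scaling.
#'
#' @param img numeric non-negative matrix.
#' @param seRadiusPx radius of the disk structuring element (default 4).
#' @param maxAreaPx2 area filter in pixels squared (default 144).
#' @param minRelIntensity background rejection level relative to the
#'   image maximum.
#' @return A data frame with \code{row}, \code{col} (centre of mass) and
#'   \code{area} (plateau area in pixels).
#' @export
detectNuclei <- function(img, seRadiusPx = 4, maxAreaPx2 = 144,
                         minRelIntensity = 0.25) {
  stopifnot(is.matrix(img))
  empty <- data.frame(row = numeric(), col = numeric(),
                      area = numeric())
  if (!length(img) || max(img) <= 0) return(empty)
  brush <- EBImage::makeBrush(2 * seRadiusPx + 1, shape = "disc")
  opened <- EBImage::opening(EBImage::Image(img), brush)
  opened <- matrix(as.numeric(opened), nrow(img), ncol(img))
  rm <- .regionalMaxima(opened)
  thr <- minRelIntensity * max(opened)
  out <- lapply(rm$maxima, function(l) {
    px <- which(rm$labels == l, arr.ind = TRUE)
    val <- opened[px[1, 1], px[1, 2]]
    if (val <= thr) return(NULL)
    data.frame(row = mean(px[, 1]), col = mean(px[, 2]),
               area = nrow(px))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out <- out[out$area <= maxAreaPx2, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit a 3-D affine transform between point sets
#'
#' Least-squares solution of \code{y = T x + T0} for the 3 x 3 linear
#' matrix \code{T} and the translation \code{T0}, given k corresponding
#' landmark pairs (columns of the inputs).
#'
#' @param src,dst 3 x k matrices of corresponding points.
#' @return A list with \code{linear} (3 x 3), \code{offset} (length 3)
#'   and \code{rmsResidual}.
#' @export
fitAffine <- function(src, dst) {
  stopifnot(is.matrix(src), is.matrix(dst), nrow(src) == 3,
            nrow(dst) == 3, ncol(src) == ncol(dst))
  k <- ncol(src)
  if (k < 4) stop("need at least 4 correspondences")
  X <- cbind(t(src), 1)
  if (qr(X)$rank < 4)
    stop("source points are rank deficient (coplanar or collinear)")
  B <- qr.solve(X, t(dst))  # 4 x 3
  Tm <- t(B[1:3, , drop = FALSE])
  T0 <- as.numeric(B[4, ])
  pred <- Tm %*% src + T0
  rms <- sqrt(mean((dst - pred)^2))
  list(linear = Tm, offset = T0, rmsResidual = rms)
}

#' Apply an affine transform to points
#'
#' @param transform list from [fitAffine()].
#' @param points 3 x k matrix.
#' @return 3 x k matrix of transformed points.
#' @export
applyAffine <- function(transform, points) {
  transform$linear %*% points + transform$offset
}

#' Fit an exponential decay to a saccade-triggered average
#'
#' Fits \code{A exp(-t / tau) + b} to the post-saccade portion of an
#' STA. The baseline \code{b} is fixed to the mean of the pre-saccade
#' baseline window; \code{A} and \code{tau} are found by constrained
#' least squares (\code{tau > 0}, \code{A >= b}). Used to estimate the
#' calcium-indicator decay constant from cells transitioning from firing
#' to quiescence; callers keep fits with \code{rSquared > 0.8}.
#'
#' @param values numeric STA values.
#' @param timeGrid numeric times (s), 0 at the saccade.
#' @param baselineWindow length-2 window (s) before the saccade used for
#'   \code{b} (default 1-2 s prior).
#' @return A list of class \code{"ExpDecayFit"} with \code{amplitude},
#'   \code{tauS}, \code{offset}, \code{rSquared}.
#' @export
fitExponentialDecay <- function(values, timeGrid,
                                baselineWindow = c(-2, -1)) {
  stopifnot(length(values) == length(timeGrid))
  post <- timeGrid >= 0 & is.finite(values)
  if (sum(post) < 5) stop("need at least 5 post-saccade samples")
  base <- values[timeGrid >= baselineWindow[1] &
                   timeGrid <= baselineWindow[2]]
  b <- if (length(base)) mean(base, na.rm = TRUE) else
    min(values[post])
  tp <- timeGrid[post]
  yp <- values[post]
  obj <- function(par) {
    A <- par[1]; tau <- par[2]
    sum((A * exp(-tp / tau) + b - yp)^2)
  }
  A0 <- max(yp[1] - b, 1e-3)
  fit <- stats::optim(c(A0, 1), obj, method = "L-BFGS-B",
                      lower = c(b, 1e-3),
                      upper = c(Inf, 1e3))
  pred <- fit$par[1] * exp(-tp / fit$par[2]) + b
  sst <- sum((yp - mean(yp))^2)
  r2 <- if (sst > 0) 1 - sum((yp - pred)^2) / sst else 0
  structure(list(amplitude = fit$par[1], tauS = fit$par[2], offset = b,
                 rSquared = max(0, r2)),
            class = "ExpDecayFit")
}

#' Median decay constant over well-fit cells
#'
#' Aggregates [fitExponentialDecay()] results: the median \code{tauS}
#' over fits with \code{rSquared} above the cutoff.
#'
#' @param fits list of \code{"ExpDecayFit"} objects.
#' @param r2Cutoff minimum r-squared (default 0.8).
#' @return Median tau in seconds (NA when no fit qualifies).
#' @export
medianTauWellFit <- function(fits, r2Cutoff = 0.8) {
  tau <- vapply(fits, function(f) {
    if (f$rSquared > r2Cutoff) f$tauS else NA_real_
  }, numeric(1))
  stats::median(tau, na.rm = TRUE)
}
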