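#' Median-filter an eye-position trace
#'
#' Replaces each sample by the running median over a centred window whose
#' order corresponds to \code{windowS} seconds at the trace's sampling
#' rate (forced odd). Robustly removes tracking glitches while preserving
#' the step structure of saccades.
#'
#' @param trace an [EyeTrace-class].
#' @param windowS window length in seconds (default 0.5).
#' @return A filtered [EyeTrace-class] of the same length.
#' @export
medianFilterPosition <- function(trace, windowS = 0.5) {
  stopifnot(is(trace, "EyeTrace"), windowS > 0)
  n <- length(trace)
  if (n == 0) stop("empty trace")
  if (n == 1) return(trace)
  fs <- 1 / stats::median(diff(traceTime(trace)))
  k <- round(windowS * fs)
  if (k %% 2 == 0) k <- k + 1
  k <- max(1, min(k, if (n %% 2 == 1) n else n - 1))
  filt <- if (k <= 1) tracePosition(trace) else
    as.numeric(stats::runmed(tracePosition(trace), k,
                             endrule = "median"))
  EyeTrace(traceTime(trace), filt, eyeLabel(trace))
}

#' Detect saccades from an eye-position trace
#'
#' Velocity-threshold saccade detection. Eye velocity is the first
#' difference of the median-filtered position divided by the sample
#' interval. The threshold is \code{max(mean(|v|) + 3 sd(v), 10)} deg/s.
#' A run of consecutive supra-threshold samples is one candidate event,
#' timed at its first sample. Candidate events closer than
#' \code{minGapS} to the previously accepted event are discarded as
#' body-movement artefacts (the later event of the pair is dropped).
#'
#' @param trace an [EyeTrace-class].
#' @param windowS median-filter window (s) applied before
#'   differentiation.
#' @param minVelocity floor on the velocity threshold (deg/s).
#' @param minGapS minimum accepted inter-event interval (s).
#' @return A data frame with one row per saccade: \code{onset} (s),
#'   \code{direction} ("L"/"R"), \code{amplitude} (deg, positive) and
#'   \code{peakVelocity} (deg/s, signed).
#' @examples
#' sim <- genEyeTrace(behaviorConfig(durationS = 300, seed = 2))
#' ev <- detectSaccades(sim$trace)
#' head(ev)
#' @export
detectSaccades <- function(trace, windowS = 0.5, minVelocity = 10,
                           minGapS = 1.4) {
  stopifnot(is(trace, "EyeTrace"))
  if (length(trace) < 2) stop("need at least 2 samples")
  filt <- medianFilterPosition(trace, windowS)
  tt <- traceTime(filt)
  pp <- tracePosition(filt)
  v <- diff(pp) / diff(tt)
  if (all(!is.finite(v))) stop("velocity is all NA")
  thr <- max(mean(abs(v), na.rm = TRUE) +
               3 * stats::sd(v, na.rm = TRUE), minVelocity)
  supra <- is.finite(v) & abs(v) > thr

  empty <- data.frame(onset = numeric(), direction = character(),
                      amplitude = numeric(), peakVelocity = numeric(),
                      stringsAsFactors = FALSE)
  if (!any(supra)) return(empty)

  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- cbind(starts[r$values], ends[r$values])

  out <- lapply(seq_len(nrow(runs)), function(i) {
    i0 <- runs[i, 1]; i1 <- runs[i, 2]
    vseg <- v[i0:i1]
    pk <- vseg[which.max(abs(vseg))]
    data.frame(onset = tt[i0], direction = .dirToChar(sign(pk)),
               amplitude = abs(pp[i1 + 1] - pp[i0]), peakVelocity = pk,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)

  keep <- logical(nrow(out))
  lastAccepted <- -Inf
  for (i in seq_len(nrow(out))) {
    if (out$onset[i] - lastAccepted > minGapS) {
      keep[i] <- TRUE
      lastAccepted <- out$onset[i]
    }
  }
  out <- out[keep & out$amplitude > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Segment fixations between detected saccades
#'
#' One fixation per adjacent pair of saccade events, carrying the
#' directions of the flanking saccades.
#'
#' @param events saccade data frame from [detectSaccades()].
#' @return A data frame with \code{start}, \code{end}, \code{duration}
#'   (s) and \code{precedingDirection}/\code{followingDirection}.
#' @export
segmentFixations <- function(events) {
  if (nrow(events) < 2)
    return(data.frame(start = numeric(), end = numeric(),
                      duration = numeric(),
                      precedingDirection = character(),
                      followingDirection = character(),
                      stringsAsFactors = FALSE))
  stopifnot(!is.unsorted(events$onset))
  n <- nrow(events)
  data.frame(start = events$onset[-n], end = events$onset[-1],
             duration = diff(events$onset),
             precedingDirection = events$direction[-n],
             followingDirection = events$direction[-1],
             stringsAsFactors = FALSE)
}

#' Behavioural summary statistics
#'
#' Summarises a saccade/fixation segmentation: fixation-duration
#' quantiles, the fraction of saccades made in the same direction as the
#' previous saccade, and amplitude medians split by whether the saccade
#' repeated or reversed the previous direction.
#'
#' @param events saccade data frame from [detectSaccades()].
#' @param fixations fixation data frame from [segmentFixations()].
#' @return A list with \code{medianFixationS},
#'   \code{fixationQuantilesS} (1st/99th percentiles),
#'   \code{sameDirectionFraction}, \code{nSameTransitions},
#'   \code{amplitudeMedianDeg}, and \code{amplitudeMediansByHistory}
#'   (same/opposite).
#' @export
behaviorSummary <- function(events, fixations) {
  if (!nrow(events)) stop("no events")
  same <- if (nrow(events) >= 2)
    events$direction[-1] == events$direction[-nrow(events)] else logical()
  sameAmp <- events$amplitude[-1][same]
  oppAmp <- events$amplitude[-1][!same]
  list(medianFixationS = stats::median(fixations$duration),
       fixationQuantilesS = stats::quantile(fixations$duration,
                                            c(0.01, 0.99), names = FALSE),
       sameDirectionFraction = mean(same),
       nSameTransitions = length(same),
       amplitudeMedianDeg = stats::median(events$amplitude),
       amplitudeMediansByHistory = c(
         same = stats::median(sameAmp),
         opposite = stats::median(oppAmp)))
}

#' Power spectral density of eye position
#'
#' Welch-style PSD: the trace is linearly resampled to a uniform grid at
#' its median sampling interval, split into half-overlapping
#' Hann-windowed segments, and segment periodograms are averaged. Also
#' reports the frequency below which a given fraction of the non-DC
#' power lies.
#'
#' @param trace an [EyeTrace-class].
#' @param segmentS segment length in seconds.
#' @param powerFraction cumulative non-DC power fraction to locate
#'   (default 0.95).
#' @return A list with \code{freq} (Hz), \code{psd} (deg^2/Hz),
#'   \code{cumulativeFraction}, \code{freqAtFraction} (Hz) and
#'   \code{peakFreq} (non-DC peak, Hz).
#' @export
positionPowerSpectrum <- function(trace, segmentS = 100,
                                  powerFraction = 0.95) {
  stopifnot(is(trace, "EyeTrace"))
  tt <- traceTime(trace)
  pp <- tracePosition(trace)
  dt <- stats::median(diff(tt))
  grid <- seq(min(tt), max(tt), by = dt)
  x <- stats::approx(tt, pp, xout = grid, rule = 2, ties = "ordered")$y
  nseg <- max(8, round(segmentS / dt))
  if (length(x) < nseg) stop("trace shorter than one segment")
  step <- floor(nseg / 2)
  starts <- seq(1, length(x) - nseg + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / (nseg + 1)))  # Hann
  U <- sum(w^2)
  nf <- floor(nseg / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    P <- abs(stats::fft(seg))^2 * dt / U  # two-sided density
    acc <- acc + P[seq_len(nf)]
  }
  psd <- acc / length(starts)
  # fold two-sided into one-sided
  if (nseg %% 2 == 0) {
    psd[2:(nf - 1)] <- 2 * psd[2:(nf - 1)]
  } else {
    psd[2:nf] <- 2 * psd[2:nf]
  }
  freq <- (seq_len(nf) - 1) / (nseg * dt)
  nondc <- psd[-1]
  cumfrac <- cumsum(nondc) / sum(nondc)
  fAt <- freq[-1][which(cumfrac >= powerFraction)[1]]
  list(freq = freq, psd = psd,
       cumulativeFraction = c(0, cumfrac),
       freqAtFraction = fAt,
       peakFreq = freq[-1][which.max(nondc)])
}
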