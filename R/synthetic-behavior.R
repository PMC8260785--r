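#' Behavioural simulation configuration
#'
#' Parameters of the synthetic spontaneous-saccade generator. Defaults
#' reproduce the statistics of spontaneous eye movements in larval
#' zebrafish kept in the dark: successive saccades repeat the previous
#' direction about 23\% of the time, fixation durations follow a
#' truncated log-normal with median 11.4 s and 1st/99th percentiles near
#' 2 and 50 s, and saccade amplitudes have median 8 deg when the saccade
#' repeats the previous direction and 13 deg when it reverses.
#'
#' @param sampleRateHz eye-position sampling rate (Hz).
#' @param pSameDirection probability that a saccade repeats the direction
#'   of the previous one.
#' @param fixationMedianS median fixation duration (s).
#' @param fixationSdlog shape (log-scale SD) of the log-normal fixation
#'   distribution; the default puts the 1st/99th percentiles near 2 and
#'   50 s.
#' @param fixationRangeS truncation bounds (s) on fixation durations.
#' @param amplitudeMediansDeg length-2 vector: median amplitude for
#'   same-direction and opposite-direction saccades (degrees).
#' @param amplitudeSdlog log-scale SD of the amplitude distribution.
#' @param saccadeRiseTimeS duration over which the eye traverses a
#'   saccade, rendered as a linear ramp (s).
#' @param positionNoiseDeg SD of additive Gaussian position noise (deg).
#' @param durationS total simulated time (s).
#' @param maxPositionDeg soft bound on absolute eye position; amplitudes
#'   are capped so the eye stays within it.
#' @param seed integer RNG seed.
#' @return A list of class \code{"BehaviorConfig"}.
#' @export
behaviorConfig <- function(sampleRateHz = 13, pSameDirection = 0.23,
                           fixationMedianS = 11.4, fixationSdlog = 0.69,
                           fixationRangeS = c(1.5, 60),
                           amplitudeMediansDeg = c(same = 8, opposite = 13),
                           amplitudeSdlog = 0.35,
                           saccadeRiseTimeS = 0.15,
                           positionNoiseDeg = 0.1, durationS = 600,
                           maxPositionDeg = 35, seed = 1L) {
  stopifnot(sampleRateHz > 0, pSameDirection >= 0, pSameDirection <= 1,
            fixationMedianS > 0, fixationSdlog >= 0,
            length(fixationRangeS) == 2, fixationRangeS[1] > 0,
            length(amplitudeMediansDeg) == 2,
            all(amplitudeMediansDeg > 0), saccadeRiseTimeS > 0,
            positionNoiseDeg >= 0, durationS > 0)
  structure(list(sampleRateHz = sampleRateHz,
                 pSameDirection = pSameDirection,
                 fixationMedianS = fixationMedianS,
                 fixationSdlog = fixationSdlog,
                 fixationRangeS = fixationRangeS,
                 amplitudeMediansDeg = amplitudeMediansDeg,
                 amplitudeSdlog = amplitudeSdlog,
                 saccadeRiseTimeS = saccadeRiseTimeS,
                 positionNoiseDeg = positionNoiseDeg,
                 durationS = durationS,
                 maxPositionDeg = maxPositionDeg,
                 seed = as.integer(seed)),
            class = "BehaviorConfig")
}

# truncated log-normal fixation durations, parameterised by the median
.sampleFixations <- function(n, cfg) {
  mu <- log(cfg$fixationMedianS)
  out <- numeric(0)
  while (length(out) < n) {
    d <- stats::rlnorm(2 * n, meanlog = mu, sdlog = cfg$fixationSdlog)
    d <- d[d >= cfg$fixationRangeS[1] & d <= cfg$fixationRangeS[2]]
    out <- c(out, d)
  }
  out[seq_len(n)]
}

#' Generate a synthetic eye-position trace with ground truth
#'
#' Simulates alternating saccade/fixation behaviour: a Markov direction
#' sequence where the next saccade repeats the previous direction with
#' probability \code{pSameDirection}, fixation durations drawn from a
#' truncated log-normal, and direction-history-dependent amplitudes. Eye
#' position is piecewise-constant with linear ramps of
#' \code{saccadeRiseTimeS} at each saccade, plus additive Gaussian noise.
#'
#' @param cfg a [behaviorConfig()] list.
#' @param fixationDurations optional numeric vector overriding the random
#'   fixation durations; the trace then contains exactly
#'   \code{length(fixationDurations) + 1} saccades (one bounding each
#'   end).
#' @return A list with elements \code{trace} (an [EyeTrace-class]) and
#'   \code{truth}, a list holding \code{saccadeTimes}, \code{directions}
#'   (+1 right / -1 left), \code{amplitudes} and a \code{fixations}
#'   data frame (start, end, duration, flanking directions).
#' @examples
#' sim <- genEyeTrace(behaviorConfig(durationS = 300, seed = 7))
#' length(sim$truth$saccadeTimes)
#' @export
genEyeTrace <- function(cfg, fixationDurations = NULL) {
  stopifnot(inherits(cfg, "BehaviorConfig"))
  set.seed(cfg$seed)
  pad <- 3  # quiet lead-in/out so every saccade has flanking data

  if (is.null(fixationDurations)) {
    if (cfg$durationS < cfg$fixationRangeS[1] + 2 * pad)
      stop("durationS too short for a single fixation")
    # draw fixations until they tile the requested duration
    durs <- numeric(0)
    while (sum(durs) < cfg$durationS - 2 * pad)
      durs <- c(durs, .sampleFixations(64, cfg))
    durs <- durs[cumsum(durs) <= cfg$durationS - 2 * pad]
    if (!length(durs)) durs <- .sampleFixations(1, cfg)
  } else {
    stopifnot(all(fixationDurations > 0))
    durs <- fixationDurations
  }

  nSacc <- length(durs) + 1
  saccadeTimes <- pad + cumsum(c(0, durs))

  directions <- integer(nSacc)
  directions[1] <- sample(c(-1L, 1L), 1)
  if (nSacc > 1) {
    same <- stats::runif(nSacc - 1) < cfg$pSameDirection
    for (k in 2:nSacc)
      directions[k] <- if (same[k - 1]) directions[k - 1] else
        -directions[k - 1]
  }

  # Reversal saccades aim at a mirrored target eccentricity, which keeps
  # the position walk stationary and yields larger reversal amplitudes
  # (~2x the target eccentricity, matching the configured opposite-
  # direction median); same-direction saccades move the eye further by a
  # log-normal amplitude draw, truncated to the oculomotor range with a
  # 4-deg floor that keeps them supra-threshold for the velocity
  # detector.
  amplitudes <- numeric(nSacc)
  pos <- numeric(nSacc + 1)  # plateau levels, pos[1] pre-first-saccade
  pos[1] <- 0
  targetMed <- cfg$amplitudeMediansDeg[[2]] / 2
  for (k in seq_len(nSacc)) {
    d <- directions[k]
    if (k > 1 && d == directions[k - 1]) {
      a <- stats::rlnorm(1, meanlog = log(cfg$amplitudeMediansDeg[[1]]),
                         sdlog = cfg$amplitudeSdlog)
      cap <- cfg$maxPositionDeg - d * pos[k]
      if (cap >= 4) {
        tries <- 0
        while ((a < 4 || a > cap) && tries < 50) {
          a <- stats::rlnorm(1,
                             meanlog = log(cfg$amplitudeMediansDeg[[1]]),
                             sdlog = cfg$amplitudeSdlog)
          tries <- tries + 1
        }
        a <- max(4, min(a, cap))
      } else {
        a <- max(min(cap, 2), 1)
      }
    } else {
      ecc <- stats::rlnorm(1, meanlog = log(targetMed),
                           sdlog = cfg$amplitudeSdlog)
      a <- max(4, d * (d * ecc - pos[k]))
    }
    amplitudes[k] <- a
    pos[k + 1] <- pos[k] + d * a
  }

  totalDur <- saccadeTimes[nSacc] + pad
  time <- seq(0, totalDur, by = 1 / cfg$sampleRateHz)
  # knots: plateau value up to each saccade, ramp over the rise time
  knotX <- c(0, as.vector(rbind(saccadeTimes,
                                saccadeTimes + cfg$saccadeRiseTimeS)),
             totalDur)
  knotY <- c(pos[1], as.vector(rbind(pos[seq_len(nSacc)],
                                     pos[seq_len(nSacc) + 1])),
             pos[nSacc + 1])
  position <- stats::approx(knotX, knotY, xout = time, rule = 2,
                            ties = "ordered")$y
  if (cfg$positionNoiseDeg > 0)
    position <- position + stats::rnorm(length(position), 0,
                                        cfg$positionNoiseDeg)

  fixations <- if (nSacc >= 2)
    data.frame(start = saccadeTimes[-nSacc], end = saccadeTimes[-1],
               duration = diff(saccadeTimes),
               precedingDirection = .dirToChar(directions[-nSacc]),
               followingDirection = .dirToChar(directions[-1]),
               stringsAsFactors = FALSE)
  else
    data.frame(start = numeric(), end = numeric(), duration = numeric(),
               precedingDirection = character(),
               followingDirection = character())

  list(trace = EyeTrace(time, position, "left"),
       truth = list(saccadeTimes = saccadeTimes, directions = directions,
                    amplitudes = amplitudes, fixations = fixations,
                    config = cfg))
}

#' Generate synthetic ablation experiment records
#'
#' Draws per-animal fixation-duration samples before and after an
#' ablation. Post-ablation durations come from the same log-normal family
#' with the median inflated by \code{effect} (e.g. 0.5 for a 50\%
#' increase). Post-ablation saccade rates per direction are derived from
#' the simulated durations, for use with [excludeNonsaccading()].
#'
#' @param animalIds character vector of animal identifiers.
#' @param group group label recycled across animals.
#' @param effects per-animal fractional change in median fixation
#'   duration (recycled).
#' @param nBefore,nAfter per-animal fixation counts (recycled; counts
#'   jitter is the caller's job).
#' @param medianBeforeS baseline median fixation duration (s).
#' @param sdlog log-scale SD of the duration distribution.
#' @param seed integer RNG seed.
#' @return A list of experiment records, each a list with fields
#'   \code{animalId}, \code{group}, \code{before}, \code{after} (duration
#'   vectors, s) and \code{afterRatePerDirection} (saccades/minute,
#'   length 2).
#' @export
genAblationExperiments <- function(animalIds, group = "cluster",
                                   effects = 0, nBefore = 100,
                                   nAfter = 100, medianBeforeS = 11.4,
                                   sdlog = 0.69, seed = 1L) {
  set.seed(as.integer(seed))
  n <- length(animalIds)
  effects <- rep_len(effects, n)
  nBefore <- rep_len(nBefore, n)
  nAfter <- rep_len(nAfter, n)
  group <- rep_len(group, n)
  lapply(seq_len(n), function(j) {
    before <- stats::rlnorm(nBefore[j], log(medianBeforeS), sdlog)
    after <- stats::rlnorm(nAfter[j],
                           log(medianBeforeS * (1 + effects[j])), sdlog)
    # alternating saccades: each direction fires about every other
    # fixation
    ratePerDir <- (nAfter[j] / 2) / (sum(after) / 60)
    list(animalId = animalIds[j], group = group[j], before = before,
         after = after,
         afterRatePerDirection = rep(ratePerDir, 2))
  })
}
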