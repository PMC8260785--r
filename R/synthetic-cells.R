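#' SR-cell simulation configuration
#'
#' Parameters for generating a synthetic pre-saccadic rise (SR) neuron.
#' Within each fixation that ends in a saccade in the cell's preferred
#' direction, deconvolved activity rises linearly from a rise onset to a
#' common threshold \code{kappa} reached exactly at the saccade, so that
#' ground-truth slope x rise duration = kappa (before slope noise). The
#' rise onset is a Beta-distributed fraction of the fixation, which
#' reproduces the broad distribution of normalised rise times seen in
#' these neurons. Fluorescence is the deconvolved trace passed through a
#' discrete exponential (AR(1)) calcium kernel with decay constant
#' \code{tauS}, plus Gaussian noise.
#'
#' @param kappa positive activity threshold (deconvolved units); the
#'   generator's unit convention is kappa = 1.
#' @param betaShape1,betaShape2 shape parameters of the Beta distribution
#'   for the rise-onset fraction of the fixation (onset =
#'   fixation duration x u). The defaults put the median rise time
#'   before saccade near 5 s at the default behaviour statistics.
#' @param riseOnsetFraction optional fixed onset fraction replacing the
#'   Beta draw; 0 makes every rise span the whole fixation, so the
#'   population average is an exact linear ramp (useful for testing the
#'   ramp-to-threshold predictor under model-consistent conditions).
#' @param riseTimeBeforeS optional saccade-locked onset: the rise starts
#'   this many seconds before the upcoming saccade (clipped to the
#'   fixation), overriding both Beta and fixed-fraction models.
#' @param slopeNoiseCV coefficient of variation of multiplicative slope
#'   noise (0 = noise free; the ramp then ends exactly at kappa).
#' @param preferredDirection \code{"L"} or \code{"R"}.
#' @param tauS calcium-indicator decay constant (s), default 1.3.
#' @param noiseSD SD of Gaussian noise added to fluorescence.
#' @param sampleRateHz imaging frame rate (Hz), default 0.98.
#' @param seed integer RNG seed.
#' @return A list of class \code{"SRCellConfig"}.
#' @export
srCellConfig <- function(kappa = 1, betaShape1 = 2, betaShape2 = 1.6,
                         riseOnsetFraction = NULL,
                         riseTimeBeforeS = NULL,
                         slopeNoiseCV = 0, preferredDirection = "L",
                         tauS = 1.3, noiseSD = 0, sampleRateHz = 0.98,
                         seed = 1L) {
  if (!is.finite(kappa) || kappa <= 0)
    stop("kappa must be positive")
  stopifnot(preferredDirection %in% c("L", "R"), tauS > 0,
            noiseSD >= 0, sampleRateHz > 0, slopeNoiseCV >= 0)
  structure(list(kappa = kappa, betaShape1 = betaShape1,
                 betaShape2 = betaShape2,
                 riseOnsetFraction = riseOnsetFraction,
                 riseTimeBeforeS = riseTimeBeforeS,
                 slopeNoiseCV = slopeNoiseCV,
                 preferredDirection = preferredDirection, tauS = tauS,
                 noiseSD = noiseSD, sampleRateHz = sampleRateHz,
                 seed = as.integer(seed)),
            class = "SRCellConfig")
}

#' Apply the exponential calcium kernel
#'
#' Forward model mapping deconvolved activity to fluorescence: the
#' discrete AR(1) recursion F[t] = g * F[t-1] + s[t] with
#' g = exp(-dt / tauS), equivalent to convolution with a sampled
#' exponential decay kernel of unit peak.
#'
#' @param deconv numeric activity vector.
#' @param dt sample interval (s).
#' @param tauS decay constant (s).
#' @return Numeric fluorescence vector of the same length.
#' @export
calciumKernel <- function(deconv, dt, tauS = 1.3) {
  stopifnot(dt > 0, tauS > 0)
  g <- exp(-dt / tauS)
  as.numeric(stats::filter(deconv, filter = g, method = "recursive"))
}

# evaluate the SR deconvolved ramp on arbitrary times given the event
# table (onset, saccadeTime, slope)
.srDeconvAt <- function(t, events) {
  out <- numeric(length(t))
  for (k in seq_len(nrow(events))) {
    idx <- t > events$onset[k] & t <= events$saccadeTime[k]
    out[idx] <- events$slope[k] * (t[idx] - events$onset[k])
  }
  pmax(out, 0)
}

#' Generate a synthetic SR cell
#'
#' Builds per-fixation linear activity ramps obeying the ramp-to-threshold
#' structure described in [srCellConfig()], samples them at the imaging
#' frame rate, and convolves with the exponential calcium kernel. Sample
#' times are aligned so that every saccade time falls exactly on a
#' sample, making noise-free traces analytically checkable.
#'
#' @param cfg an [srCellConfig()] list.
#' @param truth ground-truth list from [genEyeTrace()].
#' @return A [CellTrace-class]; \code{cellMetadata(x)$events} holds the
#'   ground-truth table (fixation, onset, slope, rise duration and the
#'   deconvolved value at saccade).
#' @export
genSRCell <- function(cfg, truth) {
  stopifnot(inherits(cfg, "SRCellConfig"))
  if (is.null(truth$saccadeTimes) || !length(truth$saccadeTimes))
    stop("truth must contain at least one saccade")
  set.seed(cfg$seed)
  fx <- truth$fixations
  pref <- fx$followingDirection == cfg$preferredDirection
  ev <- fx[pref, , drop = FALSE]
  if (nrow(ev)) {
    if (!is.null(cfg$riseTimeBeforeS)) {
      onset <- pmax(ev$start + 0.2, ev$end - cfg$riseTimeBeforeS)
    } else {
      u <- if (is.null(cfg$riseOnsetFraction))
        stats::rbeta(nrow(ev), cfg$betaShape1, cfg$betaShape2)
      else rep(cfg$riseOnsetFraction, nrow(ev))
      onset <- ev$start + ev$duration * u
    }
    riseDur <- ev$end - onset
    slope <- cfg$kappa / riseDur
    if (cfg$slopeNoiseCV > 0)
      slope <- slope * pmax(0.1, 1 + stats::rnorm(nrow(ev), 0,
                                                  cfg$slopeNoiseCV))
    events <- data.frame(fixation = which(pref), onset = onset,
                         saccadeTime = ev$end, riseDuration = riseDur,
                         slope = slope,
                         deconvAtSaccade = slope * riseDur)
  } else {
    events <- data.frame(fixation = integer(), onset = numeric(),
                         saccadeTime = numeric(), riseDuration = numeric(),
                         slope = numeric(), deconvAtSaccade = numeric())
  }

  dt <- 1 / cfg$sampleRateHz
  tmax <- max(truth$saccadeTimes) + 3
  time <- seq(0, tmax, by = dt)
  # shift the grid so saccade times are sampled exactly
  if (length(truth$saccadeTimes)) {
    off <- truth$saccadeTimes[1] %% dt
    time <- time + off
    time <- time[time <= tmax]
  }
  dec <- .srDeconvAt(time, events)
  Fl <- calciumKernel(dec, dt, cfg$tauS)
  if (cfg$noiseSD > 0)
    Fl <- Fl + stats::rnorm(length(Fl), 0, cfg$noiseSD)

  CellTrace(time = time, F = Fl, deconv = dec,
            cellId = sprintf("SR_%s_seed%d", cfg$preferredDirection,
                             cfg$seed),
            metadata = list(archetype = "sr", config = cfg,
                            events = events))
}

#' Generate a synthetic archetype cell
#'
#' Template cells covering the non-SR response classes seen around
#' spontaneous saccades: \code{"tonic"} cells step to a constant level
#' for the whole fixation following a preferred-direction saccade,
#' \code{"burst"} cells fire a single impulse in the sample bin
#' containing the saccade, and \code{"burst_tonic"} cells do both.
#' Fluorescence is obtained with the exponential calcium kernel.
#'
#' @param kind one of \code{"tonic"}, \code{"burst"},
#'   \code{"burst_tonic"}.
#' @param preferredDirection \code{"L"} or \code{"R"}.
#' @param truth ground-truth list from [genEyeTrace()].
#' @param amplitude deconvolved response amplitude.
#' @param noiseSD SD of Gaussian fluorescence noise.
#' @param sampleRateHz imaging frame rate (Hz).
#' @param tauS calcium decay constant (s).
#' @param seed integer RNG seed.
#' @return A [CellTrace-class] with the template recorded in its
#'   metadata.
#' @export
genArchetypeCell <- function(kind, preferredDirection = "L", truth,
                             amplitude = 1, noiseSD = 0,
                             sampleRateHz = 0.98, tauS = 1.3, seed = 1L) {
  kind <- match.arg(kind, c("tonic", "burst", "burst_tonic"))
  stopifnot(preferredDirection %in% c("L", "R"))
  set.seed(as.integer(seed))
  dt <- 1 / sampleRateHz
  tmax <- max(truth$saccadeTimes) + 3
  time <- seq(0, tmax, by = dt)
  if (length(truth$saccadeTimes)) {
    off <- truth$saccadeTimes[1] %% dt
    time <- time + off
    time <- time[time <= tmax]
  }
  dec <- numeric(length(time))
  fx <- truth$fixations
  prefSacc <- truth$saccadeTimes[.dirToChar(truth$directions) ==
                                   preferredDirection]
  if (kind %in% c("burst", "burst_tonic")) {
    for (s in prefSacc) {
      i <- which.min(abs(time - s))
      if (abs(time[i] - s) <= dt / 2 + 1e-9) dec[i] <- dec[i] + amplitude
    }
  }
  if (kind %in% c("tonic", "burst_tonic")) {
    pf <- fx[fx$precedingDirection == preferredDirection, , drop = FALSE]
    for (k in seq_len(nrow(pf)))
      dec[time > pf$start[k] & time <= pf$end[k]] <-
        dec[time > pf$start[k] & time <= pf$end[k]] + amplitude
  }
  Fl <- calciumKernel(dec, dt, tauS)
  if (noiseSD > 0) Fl <- Fl + stats::rnorm(length(Fl), 0, noiseSD)
  CellTrace(time = time, F = Fl, deconv = dec,
            cellId = sprintf("%s_%s_seed%d", kind, preferredDirection,
                             seed),
            metadata = list(archetype = kind,
                            preferredDirection = preferredDirection,
                            amplitude = amplitude))
}
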