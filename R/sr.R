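# interpolate a cell's signal at arbitrary times (linear, NA outside).
# tmax restricts the interpolation base to samples at or before that
# time (with constant right-extension), so that queries inside a
# fixation never mix in post-saccadic samples.
.cellAt <- function(cell, times, signal = "deconv", tmax = NULL) {
  tt <- traceTime(cell)
  vv <- slot(cell, signal)
  if (!is.null(tmax)) {
    keep <- tt <= tmax
    if (sum(keep) < 2) return(rep(NA_real_, length(times)))
    tt <- tt[keep]; vv <- vv[keep]
    return(stats::approx(tt, vv, xout = times, rule = c(1, 2),
                         ties = "ordered")$y)
  }
  stats::approx(tt, vv, xout = times, rule = 1, ties = "ordered")$y
}

#' Select pre-saccadic rise (SR) cells
#'
#' For each eye-movement responsive cell and each saccade direction, the
#' dF/F samples from all fixations preceding a saccade in that direction
#' are pooled with their time relative to the upcoming saccade (negative,
#' increasing towards 0). Samples within \code{excludeS} seconds of the
#' previous saccade are excluded so post-saccadic decays do not
#' contribute. A one-sided Spearman test (rho > 0, i.e. activity grows as
#' the saccade approaches) is corrected across all cells and both
#' directions with [holmBonferroni()] at family \code{alpha}. Cells
#' significant in exactly one direction are SR cells; cells significant
#' in both are flagged bidirectional and excluded from downstream SR
#' analyses.
#'
#' @param cells list of [CellTrace-class] objects (with dF/F).
#' @param fixations fixation data frame from [segmentFixations()].
#' @param alpha family-wise error rate (default 0.01).
#' @param excludeS dead time after the previous saccade (s, default 2).
#' @param minSamples minimum pooled samples per direction to test.
#' @return A data frame with \code{cellId}, \code{rhoL}, \code{rhoR},
#'   \code{pL}, \code{pR}, \code{srFlag}, \code{bidirectionalFlag} and
#'   \code{preferredDirection}.
#' @export
selectSRCells <- function(cells, fixations, alpha = 0.01, excludeS = 2,
                          minSamples = 10) {
  n <- length(cells)
  rho <- p <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("L", "R")))
  for (i in seq_len(n)) {
    cl <- cells[[i]]
    tt <- traceTime(cl)
    sig <- dFF(cl)
    if (!length(sig)) next
    for (d in c("L", "R")) {
      fx <- fixations[fixations$followingDirection == d, , drop = FALSE]
      xs <- numeric(0); ts <- numeric(0)
      for (k in seq_len(nrow(fx))) {
        # strictly pre-saccadic: the sample containing the upcoming
        # saccade already holds the saccadic burst
        idx <- tt > fx$start[k] + excludeS & tt < fx$end[k]
        xs <- c(xs, sig[idx])
        ts <- c(ts, tt[idx] - fx$end[k])
      }
      if (length(xs) < minSamples) next
      sp <- .spearmanGreater(xs, ts)
      rho[i, d] <- sp$rho
      p[i, d] <- sp$p
    }
  }
  rej <- matrix(holmBonferroni(as.vector(p), alpha = alpha, N = 2L * n),
                n, 2)
  both <- rej[, 1] & rej[, 2]
  one <- xor(rej[, 1], rej[, 2])
  pref <- rep(NA_character_, n)
  pref[one] <- ifelse(rej[one, 1], "L", "R")
  ids <- vapply(cells, cellId, character(1))
  data.frame(cellId = ids, rhoL = rho[, 1], rhoR = rho[, 2],
             pL = p[, 1], pR = p[, 2], srFlag = one,
             bidirectionalFlag = both, preferredDirection = pref,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Measure activity rise times within fixations
#'
#' The rise onset in a fixation is the last sample before the first
#' sample whose deconvolved activity exceeds \code{threshold}. Reports
#' the onset relative to both the previous and upcoming saccade and the
#' normalised rise time (onset relative to upcoming saccade divided by
#' fixation duration, in [-1, 0]). Fixations whose activity never
#' crosses threshold yield no event. The default threshold (0.1) is on
#' the scale where the ramp threshold kappa is about 1; rescale it
#' proportionally for recordings on other scales.
#'
#' @param cell a [CellTrace-class] with deconvolved activity.
#' @param fixations fixation data frame (optionally pre-filtered to the
#'   cell's preferred direction).
#' @param threshold rise threshold in deconvolved units.
#' @return A data frame with one row per detected rise:
#'   \code{fixation}, \code{onset} (s), \code{riseBeforeSaccadeS},
#'   \code{riseAfterPreviousS}, \code{normalizedRise}.
#' @export
measureRiseTimes <- function(cell, fixations, threshold = 0.1) {
  tt <- traceTime(cell)
  dc <- deconv(cell)
  out <- lapply(seq_len(nrow(fixations)), function(k) {
    idx <- which(tt >= fixations$start[k] & tt <= fixations$end[k])
    if (length(idx) < 2) return(NULL)
    supra <- which(dc[idx] > threshold)
    if (!length(supra) || supra[1] == 1) {
      if (!length(supra)) return(NULL)
      onsetI <- idx[1]  # already rising at fixation start
    } else {
      onsetI <- idx[supra[1] - 1]
    }
    dur <- fixations$duration[k]
    before <- fixations$end[k] - tt[onsetI]
    data.frame(fixation = k, onset = tt[onsetI],
               riseBeforeSaccadeS = before,
               riseAfterPreviousS = tt[onsetI] - fixations$start[k],
               normalizedRise = max(-1, min(0, -before / dur)))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(fixation = integer(), onset = numeric(),
                      riseBeforeSaccadeS = numeric(),
                      riseAfterPreviousS = numeric(),
                      normalizedRise = numeric())
  out
}

#' Slope of the pre-saccadic rise
#'
#' Ordinary least-squares slope of deconvolved activity against time
#' over [onset, saccade]. The fit quality is the correlation between the
#' regression fit and the data; events with \code{fitCC <= 0.4} should
#' be excluded downstream as poorly approximated by a line.
#'
#' @param cell a [CellTrace-class].
#' @param onset rise-onset time (s).
#' @param saccadeTime upcoming saccade time (s).
#' @return A list with \code{slope} (units/s), \code{fitCC} and
#'   \code{n}; NULL when fewer than 3 samples are available.
#' @export
measureSlope <- function(cell, onset, saccadeTime) {
  tt <- traceTime(cell)
  dc <- deconv(cell)
  idx <- which(tt >= onset & tt <= saccadeTime)
  if (length(idx) < 3) return(NULL)
  x <- tt[idx]; y <- dc[idx]
  fit <- stats::lm(y ~ x)
  cc <- if (stats::sd(y) == 0) 0 else
    stats::cor(stats::fitted(fit), y)
  cf <- stats::coef(fit)
  list(slope = unname(cf[2]), fitCC = cc, n = length(idx),
       valueAtSaccade = unname(cf[1] + cf[2] * saccadeTime))
}

#' Rise events for one SR cell
#'
#' Combines [measureRiseTimes()] and [measureSlope()] over the fixations
#' preceding saccades in the cell's preferred direction.
#'
#' @param cell a [CellTrace-class].
#' @param fixations fixation data frame.
#' @param preferredDirection \code{"L"} or \code{"R"}.
#' @param threshold rise threshold (deconvolved units).
#' @param ccMin minimum regression-fit correlation to keep an event.
#' @return Data frame of rise events with slope columns appended
#'   (\code{slope}, \code{fitCC}, \code{deconvAtSaccade},
#'   \code{fixationDuration}).
#' @export
riseEvents <- function(cell, fixations, preferredDirection,
                       threshold = 0.1, ccMin = 0.4) {
  fx <- fixations[fixations$followingDirection == preferredDirection, ,
                  drop = FALSE]
  rt <- measureRiseTimes(cell, fx, threshold)
  if (!nrow(rt)) {
    rt$slope <- rt$fitCC <- rt$deconvAtSaccade <-
      rt$fixationDuration <- numeric(0)
    return(rt)
  }
  keep <- logical(nrow(rt))
  rt$slope <- rt$fitCC <- rt$deconvAtSaccade <-
    rt$fixationDuration <- NA_real_
  for (k in seq_len(nrow(rt))) {
    fxk <- fx[rt$fixation[k], ]
    sl <- measureSlope(cell, rt$onset[k], fxk$end)
    if (is.null(sl)) next
    rt$slope[k] <- sl$slope
    rt$fitCC[k] <- sl$fitCC
    # the ramp value reached at the saccade, read off the regression
    # line (plain interpolation would mix in the post-saccadic zero)
    rt$deconvAtSaccade[k] <- sl$valueAtSaccade
    rt$fixationDuration[k] <- fxk$duration
    keep[k] <- is.finite(sl$fitCC) && sl$fitCC > ccMin
  }
  out <- rt[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ROC area between signal and noise value distributions; ties count 1/2
# (equivalent to the normalised Wilcoxon rank-sum statistic)
.rocArea <- function(signal, noise) {
  n1 <- length(signal); n2 <- length(noise)
  if (!n1 || !n2) return(NA_real_)
  r <- rank(c(signal, noise))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Choice probability of upcoming saccade direction
#'
#' At each time before the upcoming saccade, compares the distribution
#' of interpolated SR activity preceding preferred-direction saccades
#' (signal) with activity preceding non-preferred saccades (noise) using
#' the ROC area; 0.5 means activity carries no direction information.
#' Activity is linearly interpolated onto a 1/3-s grid anchored at the
#' upcoming saccade and restricted to the enclosing fixation. With
#' \code{poolSize > 1}, cells sharing a preferred direction are randomly
#' partitioned into disjoint groups of that size whose activity is
#' averaged per fixation before the comparison; groupings are resampled
#' and the CP averaged across them. The SEM is taken across CPs
#' conditioned on integer fixation durations 2-20 s (within 0.5 s).
#'
#' @param cells list of SR [CellTrace-class] objects.
#' @param preferredDirections character vector ("L"/"R") aligned with
#'   \code{cells}.
#' @param fixations fixation data frame.
#' @param poolSize cells per population average (1, 4, 16, ...).
#' @param tauMaxS how far before the saccade to evaluate (s).
#' @param nGroupings random disjoint groupings to average over when
#'   pooling (default 100).
#' @param conditionDurations integer durations (s) used for the SEM.
#' @param seed integer RNG seed for the groupings.
#' @return A list of class \code{"CPCurve"}: \code{timeBeforeS},
#'   \code{cp}, \code{sem}, \code{poolSize}, \code{nSignal},
#'   \code{nNoise}.
#' @export
choiceProbability <- function(cells, preferredDirections, fixations,
                              poolSize = 1, tauMaxS = 5,
                              nGroupings = 100,
                              conditionDurations = 2:20, seed = 1L) {
  stopifnot(length(cells) >= 2,
            length(preferredDirections) == length(cells))
  set.seed(as.integer(seed))
  taus <- seq(0, tauMaxS, by = 1/3)
  nF <- nrow(fixations)
  nC <- length(cells)
  # activity[cell, fixation, tau]: NA when tau exceeds the fixation
  act <- array(NA_real_, c(nC, nF, length(taus)))
  for (i in seq_len(nC)) {
    for (j in seq_len(nF)) {
      ok <- taus <= fixations$duration[j]
      if (!any(ok)) next
      act[i, j, ok] <- .cellAt(cells[[i]],
                               fixations$end[j] - taus[ok],
                               tmax = fixations$end[j])
    }
  }
  dirOf <- fixations$followingDirection

  cpFromGroups <- function(groupAct, groupPref, fixSel) {
    vapply(seq_along(taus), function(ti) {
      sig <- noi <- numeric(0)
      for (g in seq_len(nrow(groupAct))) {
        v <- groupAct[g, fixSel, ti]
        lab <- dirOf[fixSel]
        sig <- c(sig, v[lab == groupPref[g] & is.finite(v)])
        noi <- c(noi, v[lab != groupPref[g] & is.finite(v)])
      }
      .rocArea(sig, noi)
    }, numeric(1))
  }

  oneGrouping <- function() {
    mats <- list(); gPref <- character(0)
    for (d in c("L", "R")) {
      members <- which(preferredDirections == d)
      if (length(members) < poolSize) next
      perm <- sample(members)
      nG <- floor(length(perm) / poolSize)
      for (g in seq_len(nG)) {
        mem <- perm[(g - 1) * poolSize + seq_len(poolSize)]
        mats[[length(mats) + 1]] <-
          apply(act[mem, , , drop = FALSE], c(2, 3), mean)
        gPref <- c(gPref, d)
      }
    }
    if (!length(mats)) return(list(act = NULL, pref = character(0)))
    gAct <- array(NA_real_, c(length(mats), nF, length(taus)))
    for (g in seq_along(mats)) gAct[g, , ] <- mats[[g]]
    list(act = gAct, pref = gPref)
  }

  nGr <- if (poolSize == 1) 1 else nGroupings
  allFix <- seq_len(nF)
  cpAcc <- matrix(NA_real_, nGr, length(taus))
  cpByDur <- array(NA_real_, c(nGr, length(conditionDurations),
                               length(taus)))
  for (r in seq_len(nGr)) {
    gr <- if (poolSize == 1)
      list(act = act, pref = preferredDirections) else oneGrouping()
    if (is.null(gr$act)) stop("not enough cells for the pool size")
    cpAcc[r, ] <- cpFromGroups(gr$act, gr$pref, allFix)
    for (di in seq_along(conditionDurations)) {
      sel <- which(abs(fixations$duration -
                         conditionDurations[di]) <= 0.5)
      if (length(sel) < 2) next
      cpByDur[r, di, ] <- cpFromGroups(gr$act, gr$pref, sel)
    }
  }
  cp <- colMeans(cpAcc, na.rm = TRUE)
  durCP <- apply(cpByDur, c(2, 3), mean, na.rm = TRUE)
  sem <- apply(durCP, 2, function(v) {
    v <- v[is.finite(v)]
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  })
  structure(list(timeBeforeS = taus, cp = cp, sem = sem,
                 poolSize = poolSize,
                 nSignal = sum(dirOf %in% preferredDirections),
                 nNoise = nF),
            class = "CPCurve")
}

#' Estimate the ramp threshold kappa
#'
#' Mean deconvolved activity reached at the time of saccade across all
#' SR cells and their preferred-direction rise events. The value at the
#' saccade is taken from each event's pre-saccadic regression line
#' ([measureSlope()]), which is exact for a noise-free ramp sampled at
#' the imaging frame rate.
#'
#' @param cells list of SR [CellTrace-class] objects.
#' @param preferredDirections aligned "L"/"R" vector.
#' @param fixations fixation data frame.
#' @param threshold rise-detection threshold (deconvolved units).
#' @return Scalar kappa estimate.
#' @export
estimateKappa <- function(cells, preferredDirections, fixations,
                          threshold = 0.1) {
  vals <- numeric(0)
  for (i in seq_along(cells)) {
    ev <- riseEvents(cells[[i]], fixations, preferredDirections[i],
                     threshold = threshold)
    vals <- c(vals, ev$deconvAtSaccade)
  }
  mean(vals, na.rm = TRUE)
}

#' Population-average pre-saccadic activity per fixation duration
#'
#' For each target duration, averages interpolated deconvolved activity
#' (aligned to the upcoming saccade, 1/3-s bins) across all SR cells and
#' their preferred-direction fixations whose duration is within
#' \code{tolS} of the target.
#'
#' @param cells list of SR [CellTrace-class] objects.
#' @param preferredDirections aligned "L"/"R" vector.
#' @param fixations fixation data frame.
#' @param durations target durations (s); the default covers 3.5 to
#'   20.5 s in 18 non-overlapping 1-s steps.
#' @param tolS half-width of the duration window (s, default 0.5).
#' @return A list, one element per duration with at least 1 trial:
#'   \code{duration}, \code{t} (time since previous saccade), \code{y}
#'   (population average), \code{nTrials}.
#' @export
populationRampCurves <- function(cells, preferredDirections, fixations,
                                 durations = seq(3.5, 20.5, by = 1),
                                 tolS = 0.5) {
  dt <- 1/3
  out <- list()
  for (d in durations) {
    taus <- seq(0, d, by = dt)  # time before saccade
    rows <- list()
    for (i in seq_along(cells)) {
      fx <- fixations[fixations$followingDirection ==
                        preferredDirections[i] &
                        abs(fixations$duration - d) <= tolS, ,
                      drop = FALSE]
      for (k in seq_len(nrow(fx))) {
        ok <- taus <= fx$duration[k]
        v <- rep(NA_real_, length(taus))
        v[ok] <- .cellAt(cells[[i]], fx$end[k] - taus[ok],
                         tmax = fx$end[k])
        rows[[length(rows) + 1]] <- v
      }
    }
    if (!length(rows)) next
    m <- do.call(rbind, rows)
    y <- rev(colMeans(m, na.rm = TRUE))  # forward time order
    out[[length(out) + 1]] <- list(duration = d, t = d - rev(taus),
                                   y = y, nTrials = nrow(m))
  }
  out
}

#' Ramp-to-threshold prediction of time until saccade
#'
#' Detects the rise onset of a population trace as the first time its
#' finite-difference derivative exceeds the model's derivative
#' threshold (that time becomes t = 0), forms the running slope estimate
#' D(t) as the median derivative over (0, t], and predicts the time of
#' threshold crossing as t_r(t) = kappa / D(t). The predicted time until
#' saccade at t is t_r(t) - t, reported from one bin after onset to one
#' bin before the end of the trace.
#'
#' @param y numeric population trace on a uniform grid ending at the
#'   saccade.
#' @param model a [RampModel-class].
#' @return A data frame with \code{t} (s since onset),
#'   \code{predictedRemaining} (s; NA where the running slope is not
#'   positive), plus attribute \code{onsetIndex}; NULL when the
#'   derivative never crosses threshold.
#' @export
rampPredict <- function(y, model) {
  stopifnot(is(model, "RampModel"))
  dt <- model@dt
  dv <- diff(y) / dt
  onset <- which(dv > model@derivativeThreshold)[1]
  if (is.na(onset)) return(NULL)
  # t = 0 at grid point `onset`; derivative sample k spans (k-1, k]
  nT <- length(y) - onset  # bins available after onset
  if (nT < 2) return(NULL)
  res <- data.frame(t = numeric(0), predictedRemaining = numeric(0))
  for (k in seq_len(nT - 1)) {   # up to one bin before the end
    t <- k * dt
    D <- stats::median(dv[onset + seq_len(k) - 1])
    pred <- if (is.finite(D) && D > 0) model@kappa / D - t else
      NA_real_
    res <- rbind(res, data.frame(t = t, predictedRemaining = pred))
  }
  attr(res, "onsetIndex") <- onset
  res
}

#' Predicted versus actual time until saccade across durations
#'
#' Applies [rampPredict()] to each population curve from
#' [populationRampCurves()] and pairs predictions with the actual
#' remaining time.
#'
#' @param curves list from [populationRampCurves()].
#' @param model a [RampModel-class].
#' @return Data frame with \code{fixationDuration}, \code{t},
#'   \code{predictedRemaining}, \code{actualRemaining}.
#' @export
predictSaccadeTimes <- function(curves, model) {
  out <- lapply(curves, function(cv) {
    pr <- rampPredict(cv$y, model)
    if (is.null(pr)) return(NULL)
    onsetT <- cv$t[attr(pr, "onsetIndex")]
    data.frame(fixationDuration = cv$duration, t = pr$t,
               predictedRemaining = pr$predictedRemaining,
               actualRemaining = cv$duration - (onsetT + pr$t))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(fixationDuration = numeric(), t = numeric(),
                      predictedRemaining = numeric(),
                      actualRemaining = numeric())
  out[is.finite(out$predictedRemaining) & out$actualRemaining > 0, ,
      drop = FALSE]
}

#' Evaluate saccade-time predictions
#'
#' Pearson correlation between predicted and actual time until saccade,
#' and the timing error defined as the median of
#' |predicted - actual| / actual, as a percentage.
#'
#' @param predicted,actual numeric vectors of matched predictions.
#' @return A list with \code{cc}, \code{timingErrorPct}, \code{n} and
#'   \code{degenerate} (TRUE when predictions had zero variance, in
#'   which case cc is 0 by convention).
#' @export
evaluateRampModel <- function(predicted, actual) {
  ok <- is.finite(predicted) & is.finite(actual) & actual > 0
  predicted <- predicted[ok]; actual <- actual[ok]
  if (length(predicted) < 3)
    return(list(cc = NA_real_, timingErrorPct = NA_real_,
                n = length(predicted), degenerate = NA))
  degen <- stats::sd(predicted) == 0 || stats::sd(actual) == 0
  cc <- if (degen) 0 else stats::cor(predicted, actual)
  list(cc = cc,
       timingErrorPct = 100 * stats::median(abs(predicted - actual) /
                                              actual),
       n = length(predicted), degenerate = degen)
}

#' Ideal-observer saccade-direction accuracy
#'
#' An observer knowing only the direction transition probability guesses
#' that each saccade reverses the previous one and is correct with
#' probability 1 - pSame.
#'
#' @param pSame probability a saccade repeats the previous direction.
#' @return Accuracy in [0, 1].
#' @export
idealObserverDirection <- function(pSame) {
  stopifnot(pSame >= 0, pSame <= 1)
  1 - pSame
}

#' Empirical always-guess-opposite accuracy on a direction sequence
#'
#' @param directions vector of +/-1 (or "L"/"R") saccade directions.
#' @return Fraction of transitions where the direction reversed.
#' @export
empiricalOppositeAccuracy <- function(directions) {
  if (is.character(directions)) directions <- .charToDir(directions)
  n <- length(directions)
  if (n < 2) stop("need at least 2 saccades")
  mean(directions[-1] != directions[-n])
}

#' Ideal-observer saccade-time prediction
#'
#' Given the fixation-duration distribution and the time already elapsed
#' in the current fixation, predicts the remaining time by minimising a
#' cost over the conditional distribution of remaining time: the
#' conditional mean (mean-squared error), median (mean-absolute
#' deviation) or binned mode (all-or-none error).
#'
#' @param durations sample of fixation durations (s).
#' @param elapsed time since the previous saccade (s).
#' @param cost one of \code{"mse"}, \code{"mad"}, \code{"all_or_none"}.
#' @param binS bin width for the all-or-none mode (s, default 0.5).
#' @return Predicted remaining time (s); NA when no duration exceeds
#'   \code{elapsed}.
#' @export
idealObserverTiming <- function(durations, elapsed,
                                cost = c("mse", "mad", "all_or_none"),
                                binS = 0.5) {
  cost <- match.arg(cost)
  stopifnot(length(durations) > 0, elapsed >= 0)
  rem <- durations[durations > elapsed] - elapsed
  if (!length(rem)) return(NA_real_)
  switch(cost,
         mse = mean(rem),
         mad = stats::median(rem),
         all_or_none = {
           b <- floor(rem / binS)
           tb <- table(b)
           mode <- as.numeric(names(tb)[which.max(tb)])
           (mode + 0.5) * binS
         })
}

#' Evaluate the ideal timing observer like the ramp model
#'
#' Sweeps elapsed times through each fixation, predicts the remaining
#' time from the duration distribution, and scores predictions with
#' [evaluateRampModel()].
#'
#' @param durations fixation durations (s).
#' @param cost cost function, see [idealObserverTiming()].
#' @param stepS elapsed-time step (s).
#' @param binS all-or-none bin width (s).
#' @return Output of [evaluateRampModel()].
#' @export
evaluateIdealObserverTiming <- function(durations, cost = "all_or_none",
                                        stepS = 0.5, binS = 0.5) {
  pred <- act <- numeric(0)
  for (d in durations) {
    el <- seq(0, d - stepS, by = stepS)
    for (e in el) {
      pred <- c(pred, idealObserverTiming(durations, e, cost, binS))
      act <- c(act, d - e)
    }
  }
  evaluateRampModel(pred, act)
}

#' Cell-level train/test evaluation of the ramp fit
#'
#' Repeatedly splits the SR cells into a training fraction used to build
#' the population curves and estimate a single ramp slope (the median
#' derivative over the whole rise), and a held-out fraction on which the
#' linear ramp prediction is scored against the measured population
#' activity.
#'
#' @param cells list of SR [CellTrace-class] objects.
#' @param preferredDirections aligned "L"/"R" vector.
#' @param fixations fixation data frame.
#' @param model a [RampModel-class].
#' @param trainFraction fraction of cells used for slope estimation.
#' @param nSplits number of random splits.
#' @param seed integer RNG seed.
#' @return A list with \code{cc} (mean across splits of the correlation
#'   between predicted and held-out activity) and \code{nSplits}.
#' @export
rampModelFitCrossCells <- function(cells, preferredDirections,
                                   fixations, model,
                                   trainFraction = 0.6, nSplits = 20,
                                   seed = 1L) {
  set.seed(as.integer(seed))
  n <- length(cells)
  stopifnot(n >= 4)
  ccs <- numeric(0)
  for (s in seq_len(nSplits)) {
    tr <- sample.int(n, max(2, round(trainFraction * n)))
    te <- setdiff(seq_len(n), tr)
    if (length(te) < 1) next
    cvTr <- populationRampCurves(cells[tr], preferredDirections[tr],
                                 fixations)
    cvTe <- populationRampCurves(cells[te], preferredDirections[te],
                                 fixations)
    durTr <- vapply(cvTr, `[[`, numeric(1), "duration")
    for (cv in cvTe) {
      j <- match(cv$duration, durTr)
      if (is.na(j)) next
      yTr <- cvTr[[j]]$y
      pr <- rampPredict(yTr, model)
      if (is.null(pr)) next
      onsetI <- attr(pr, "onsetIndex")
      D <- stats::median(diff(yTr)[onsetI:(length(yTr) - 1)]) / model@dt
      if (!is.finite(D) || D <= 0) next
      tRel <- cv$t - cv$t[onsetI]
      predY <- ifelse(tRel > 0, D * tRel, 0)
      obs <- cv$y
      ok <- is.finite(obs) & tRel > 0
      if (sum(ok) >= 3 && stats::sd(predY[ok]) > 0 &&
          stats::sd(obs[ok]) > 0)
        ccs <- c(ccs, stats::cor(predY[ok], obs[ok]))
    }
  }
  list(cc = mean(ccs), nSplits = length(ccs))
}
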