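#' @import methods
NULL

#' Eye-position trace
#'
#' Container for a time series of horizontal eye position for one eye,
#' sampled at roughly 13 Hz in behaving larval zebrafish. Positions are
#' in degrees; leftward and rightward deflections have opposite sign.
#'
#' @slot time numeric, non-decreasing sample times in seconds.
#' @slot position numeric, horizontal eye position in degrees (NA allowed
#'   for masked samples).
#' @slot eye character scalar, \code{"left"} or \code{"right"}.
#'
#' @seealso [EyeTrace()] for the constructor, [detectSaccades()],
#'   [medianFilterPosition()].
#' @exportClass EyeTrace
setClass("EyeTrace",
  slots = c(time = "numeric", position = "numeric", eye = "character"))

setValidity("EyeTrace", function(object) {
  msg <- character()
  if (length(object@time) != length(object@position))
    msg <- c(msg, "time and position must have equal length")
  if (length(object@time) > 1 && any(diff(object@time) < 0))
    msg <- c(msg, "time must be non-decreasing")
  if (any(!is.finite(object@time)))
    msg <- c(msg, "time must be finite")
  if (length(object@eye) != 1 || !object@eye %in% c("left", "right"))
    msg <- c(msg, "eye must be \"left\" or \"right\"")
  if (length(msg)) msg else TRUE
})

#' Construct an EyeTrace
#'
#' @param time numeric vector of sample times (s), non-decreasing.
#' @param position numeric vector of eye positions (degrees).
#' @param eye which eye the trace was recorded from.
#' @return An [EyeTrace-class] object.
#' @examples
#' tr <- EyeTrace(time = seq(0, 10, by = 1/13),
#'                position = rep(0, 131), eye = "left")
#' tr
#' @export
EyeTrace <- function(time, position, eye = "left") {
  new("EyeTrace", time = as.numeric(time), position = as.numeric(position),
      eye = as.character(eye))
}

setMethod("show", "EyeTrace", function(object) {
  n <- length(object@time)
  dur <- if (n) diff(range(object@time)) else 0
  cat(sprintf("EyeTrace (%s eye): %d samples over %.1f s\n",
              object@eye, n, dur))
  if (n > 1)
    cat(sprintf("  sampling ~%.2f Hz, position range [%.1f, %.1f] deg\n",
                (n - 1) / dur, min(object@position, na.rm = TRUE),
                max(object@position, na.rm = TRUE)))
})

#' Single-cell calcium trace
#'
#' Raw fluorescence, dF/F and deconvolved activity for one cell, sampled
#' at the imaging frame rate (~0.98 Hz), together with its 3-D anatomical
#' location. dF/F is defined as (F - F0)/F0 with F0 the recording mean of
#' F. Deconvolved activity is the non-negative estimate of underlying
#' neural activity obtained by inverting the exponential calcium-indicator
#' kernel.
#'
#' @slot time numeric sample times (s).
#' @slot F numeric raw fluorescence (may be empty when only deconvolved
#'   activity is available).
#' @slot dFF numeric, fluorescence change normalised by the recording
#'   mean.
#' @slot deconv numeric, non-negative deconvolved activity.
#' @slot xyz numeric length-3 location in micrometres (NA when unknown).
#' @slot cellId character identifier.
#' @slot fishId character identifier of the animal.
#' @slot metadata list of generator ground truth or analysis annotations.
#'
#' @exportClass CellTrace
setClass("CellTrace",
  slots = c(time = "numeric", F = "numeric", dFF = "numeric",
            deconv = "numeric", xyz = "numeric", cellId = "character",
            fishId = "character", metadata = "list"))

setValidity("CellTrace", function(object) {
  msg <- character()
  n <- length(object@time)
  for (s in c("F", "dFF", "deconv")) {
    v <- slot(object, s)
    if (length(v) && length(v) != n)
      msg <- c(msg, sprintf("%s must be empty or match time length", s))
  }
  if (length(object@deconv) && any(object@deconv < -1e-9, na.rm = TRUE))
    msg <- c(msg, "deconv must be non-negative")
  if (length(object@xyz) != 3)
    msg <- c(msg, "xyz must have length 3")
  if (length(object@F) && length(object@dFF)) {
    f0 <- mean(object@F, na.rm = TRUE)
    if (is.finite(f0) && abs(f0) > 1e-12) {
      expect <- (object@F - f0) / f0
      if (max(abs(expect - object@dFF), na.rm = TRUE) > 1e-6)
        msg <- c(msg, "dFF inconsistent with F and its mean")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CellTrace
#'
#' If \code{F} is given and \code{dFF} is not, dF/F is computed as
#' (F - mean(F))/mean(F).
#'
#' @param time numeric sample times (s).
#' @param F raw fluorescence values (optional if \code{dFF} and
#'   \code{deconv} are supplied directly).
#' @param dFF normalised fluorescence; computed from \code{F} when
#'   missing.
#' @param deconv non-negative deconvolved activity.
#' @param xyz length-3 location in micrometres.
#' @param cellId,fishId identifiers.
#' @param metadata free-form list (e.g. generator ground truth).
#' @return A [CellTrace-class] object.
#' @export
CellTrace <- function(time, F = numeric(), dFF = numeric(),
                      deconv = numeric(), xyz = rep(NA_real_, 3),
                      cellId = "cell", fishId = "fish",
                      metadata = list()) {
  if (length(F) && !length(dFF)) dFF <- computeDFF(F)
  new("CellTrace", time = as.numeric(time), F = as.numeric(F),
      dFF = as.numeric(dFF), deconv = as.numeric(deconv),
      xyz = as.numeric(xyz), cellId = as.character(cellId),
      fishId = as.character(fishId), metadata = metadata)
}

setMethod("show", "CellTrace", function(object) {
  cat(sprintf("CellTrace %s (fish %s): %d samples", object@cellId,
              object@fishId, length(object@time)))
  have <- c("F", "dFF", "deconv")[c(length(object@F) > 0,
                                    length(object@dFF) > 0,
                                    length(object@deconv) > 0)]
  cat(sprintf(" [%s]\n", paste(have, collapse = ", ")))
})

#' Saccade-triggered average profile
#'
#' Trial matrix and average of a signal aligned to saccades of one
#' direction, on the fixed grid of 31 bins spanning -5 to +5 s in steps
#' of 1/3 s. Confidence intervals are bootstrap percentile intervals over
#' trials. A profile with fewer than the minimum number of trials is
#' marked ineligible.
#'
#' @slot direction character, \code{"L"} or \code{"R"}.
#' @slot grid numeric, the 31 bin times.
#' @slot trials numeric matrix, one row per qualifying saccade.
#' @slot mean numeric length-31 trial average.
#' @slot ciLow,ciHigh numeric length-31 bootstrap 95\% CI bounds.
#' @slot nTrials integer number of trials.
#' @slot eligible logical, TRUE when nTrials meets the minimum.
#'
#' @exportClass STAProfile
setClass("STAProfile",
  slots = c(direction = "character", grid = "numeric", trials = "matrix",
            mean = "numeric", ciLow = "numeric", ciHigh = "numeric",
            nTrials = "integer", eligible = "logical"))

setValidity("STAProfile", function(object) {
  msg <- character()
  if (!object@direction %in% c("L", "R"))
    msg <- c(msg, "direction must be \"L\" or \"R\"")
  if (length(object@grid) != 31)
    msg <- c(msg, "grid must have exactly 31 bins")
  if (object@eligible) {
    if (length(object@mean) != 31)
      msg <- c(msg, "mean must have 31 bins")
    if (ncol(object@trials) != 31)
      msg <- c(msg, "trials must have 31 columns")
    bad <- object@ciLow > object@mean + 1e-9 |
      object@ciHigh < object@mean - 1e-9
    if (length(object@ciLow) == 31 && any(bad, na.rm = TRUE))
      msg <- c(msg, "CI bounds must bracket the mean")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "STAProfile", function(object) {
  cat(sprintf("STAProfile (%s saccades): %d trials%s\n", object@direction,
              object@nTrials,
              if (object@eligible) "" else " [ineligible]"))
})

#' PCA embedding of saccade-triggered averages
#'
#' Principal components of the population of L2-normalised STAs, the
#' per-STA coefficients that reconstruct the row-centred data, and the
#' spherical-coordinate representation of the first three coefficients.
#' Phi (longitude) and Theta (latitude, 0 at the equator) are in degrees.
#'
#' @slot components matrix of orthonormal basis vectors (columns).
#' @slot coefficients matrix of per-row scores.
#' @slot center numeric column means removed before decomposition.
#' @slot varianceExplained numeric fraction of variance per component.
#' @slot normalizedCoeffs matrix, first three scores scaled to unit rows.
#' @slot phiDeg,thetaDeg numeric angles in degrees.
#'
#' @exportClass PCAEmbedding
setClass("PCAEmbedding",
  slots = c(components = "matrix", coefficients = "matrix",
            center = "numeric", varianceExplained = "numeric",
            normalizedCoeffs = "matrix", phiDeg = "numeric",
            thetaDeg = "numeric"))

setMethod("show", "PCAEmbedding", function(object) {
  cat(sprintf("PCAEmbedding: %d STAs x %d bins, %d components\n",
              nrow(object@coefficients), nrow(object@components),
              ncol(object@components)))
  ve <- cumsum(object@varianceExplained)
  cat(sprintf("  cumulative variance (3 comps): %.1f%%\n",
              100 * ve[min(3, length(ve))]))
})

#' Ramp-to-threshold model
#'
#' Parameters of the accumulator model in which population activity rises
#' linearly at rate D until it reaches a fixed threshold kappa, at which
#' point a saccade is triggered; the time to saccade is t_r = kappa / D.
#'
#' @slot kappa positive threshold in deconvolved-activity units (the mean
#'   deconvolved activity at the time of saccade across SR cells).
#' @slot dt time-bin width (s) of the interpolation grid.
#' @slot derivativeThreshold rise-onset detection threshold on the
#'   finite-difference derivative of the population trace
#'   (activity units per second).
#'
#' @exportClass RampModel
setClass("RampModel",
  slots = c(kappa = "numeric", dt = "numeric",
            derivativeThreshold = "numeric"))

setValidity("RampModel", function(object) {
  msg <- character()
  if (length(object@kappa) != 1 || !is.finite(object@kappa) ||
      object@kappa <= 0)
    msg <- c(msg, "kappa must be a positive scalar")
  if (length(object@dt) != 1 || object@dt <= 0)
    msg <- c(msg, "dt must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a RampModel
#'
#' @param kappa positive activity threshold. For recordings on the
#'   original arbitrary-unit scale the companion derivative threshold
#'   default is 35; for synthetic data generated in units where
#'   kappa = 1 pass a proportionally rescaled value (see
#'   [rampPredict()]).
#' @param dt grid step in seconds (default 1/3).
#' @param derivativeThreshold onset-detection threshold on the population
#'   derivative, in activity units per second.
#' @return A [RampModel-class] object.
#' @export
RampModel <- function(kappa, dt = 1/3, derivativeThreshold = 35) {
  new("RampModel", kappa = as.numeric(kappa), dt = as.numeric(dt),
      derivativeThreshold = as.numeric(derivativeThreshold))
}

setMethod("show", "RampModel", function(object) {
  cat(sprintf(
    "RampModel: kappa = %.3g, dt = %.3g s, derivative threshold = %.3g\n",
    object@kappa, object@dt, object@derivativeThreshold))
})
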