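#' Exclude animals that stop saccading after ablation
#'
#' Removes experiments whose post-ablation saccade rate never rises
#' strictly above the floor (one saccade per direction per minute by
#' default).
#'
#' @param experiments list of experiment records (see
#'   [genAblationExperiments()] for the fields).
#' @param rateFloor saccades per direction per minute.
#' @return The filtered list, with an \code{"excluded"} attribute
#'   naming the removed animals.
#' @export
excludeNonsaccading <- function(experiments, rateFloor = 1) {
  keep <- vapply(experiments, function(e) {
    r <- e$afterRatePerDirection
    if (is.null(r)) return(TRUE)
    all(r > rateFloor)
  }, logical(1))
  out <- experiments[keep]
  attr(out, "excluded") <- vapply(experiments[!keep],
                                  function(e) e$animalId, character(1))
  out
}

#' Resampled fractional changes in median fixation duration
#'
#' For each animal, draws repeated equal-sample measurements of the
#' fractional change in median fixation duration:
#' y = (median(after) - median(before)) / median(before), where each
#' repeat samples \code{nMin} durations per condition without
#' replacement. \code{nMin} is the minimum fixation count over all
#' animals and both conditions; the number of repeats for animal j is
#' round(min_i n_ij / nMin) (half away from zero, at least 1).
#'
#' @param experiments list of experiment records with \code{before} and
#'   \code{after} duration vectors.
#' @param nMin override for the per-repeat sample size (default: the
#'   minimum count over animals and conditions).
#' @param seed integer RNG seed.
#' @return A data frame with \code{animalId}, \code{group},
#'   \code{repeatIndex} and \code{y}; attribute \code{"nMin"} records
#'   the sample size used.
#' @export
resampleEffect <- function(experiments, nMin = NULL, seed = 1L) {
  stopifnot(length(experiments) >= 1)
  counts <- vapply(experiments, function(e)
    c(length(e$before), length(e$after)), numeric(2))
  if (any(counts < 1)) stop("every animal needs fixations in both conditions")
  if (is.null(nMin)) nMin <- min(counts)
  if (min(counts) < nMin)
    stop("nMin exceeds the smallest per-condition count")
  set.seed(as.integer(seed))
  out <- lapply(experiments, function(e) {
    nRep <- max(1, .roundHalfUp(min(length(e$before),
                                    length(e$after)) / nMin))
    ys <- vapply(seq_len(nRep), function(l) {
      b <- sample(e$before, nMin)
      a <- sample(e$after, nMin)
      (stats::median(a) - stats::median(b)) / stats::median(b)
    }, numeric(1))
    data.frame(animalId = e$animalId, group = e$group,
               repeatIndex = seq_len(nRep), y = ys,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "nMin") <- nMin
  out
}

#' Fraction of mapped SR cells inside an ablation cylinder
#'
#' Subsamples the SR-cell map so regions sampled by many animals do not
#' dominate (each point kept with probability 3 / fish count at its
#' location), then reports the fraction of retained points inside an
#' axis-aligned cylinder centred on the lesion: radius in the
#' rostro-caudal/medio-lateral plane, extent along the dorso-ventral
#' axis.
#'
#' @param points n x 3 matrix of mapped cell locations (x, y, z um; z
#'   dorso-ventral).
#' @param fishCounts number of fish sampling each point's region
#'   (scalar or length n).
#' @param lesionCenter length-3 cylinder centre (um).
#' @param radiusUm cylinder radius (default 30).
#' @param heightUm cylinder side length along z (default 60).
#' @param seed integer RNG seed for the subsampling.
#' @return Fraction in [0, 1].
#' @export
fractionAblated <- function(points, fishCounts = 3, lesionCenter,
                            radiusUm = 30, heightUm = 60, seed = 1L) {
  points <- as.matrix(points)
  if (!nrow(points)) stop("empty SR map")
  stopifnot(ncol(points) == 3, length(lesionCenter) == 3)
  fishCounts <- rep_len(fishCounts, nrow(points))
  set.seed(as.integer(seed))
  keep <- stats::runif(nrow(points)) < pmin(1, 3 / fishCounts)
  if (!any(keep)) return(0)
  pts <- points[keep, , drop = FALSE]
  inXY <- (pts[, 1] - lesionCenter[1])^2 +
    (pts[, 2] - lesionCenter[2])^2 <= radiusUm^2
  inZ <- abs(pts[, 3] - lesionCenter[3]) <= heightUm / 2
  sum(inXY & inZ) / nrow(pts)
}

#' Correlation between ablation effect and fraction of SR cells removed
#'
#' For each sample-size floor, animals with fewer fixations than the
#' floor in either condition are dropped, the resampling of
#' [resampleEffect()] is repeated \code{nBoot} times, and the Pearson
#' correlation between the effect values and the per-animal fraction of
#' SR cells ablated is computed for each resample. The resulting
#' correlation samples are compared with shuffled controls by a
#' one-sided two-sample KS test, Holm-Bonferroni corrected across
#' floors.
#'
#' @param experiments list of experiment records.
#' @param fractions named numeric vector of per-animal ablated
#'   fractions (names = animal ids).
#' @param nBoot resamples per floor (default 100).
#' @param floors sample-size floors (default 55 to 175 by 10).
#' @param alpha family-wise level for the KS tests (default 0.001).
#' @param minAnimals floors keeping fewer animals are skipped.
#' @param seed integer RNG seed.
#' @return A data frame with one row per evaluated floor:
#'   \code{floor}, \code{nAnimals}, \code{nMin}, \code{medianCC},
#'   \code{ksP}, \code{significant}; attribute \code{"meanCC"} holds
#'   the mean of the per-floor median correlations.
#' @export
correlateEffectVsFraction <- function(experiments, fractions,
                                      nBoot = 100,
                                      floors = seq(55, 175, by = 10),
                                      alpha = 0.001, minAnimals = 5,
                                      seed = 1L) {
  set.seed(as.integer(seed))
  rows <- list()
  for (fl in floors) {
    keep <- vapply(experiments, function(e)
      min(length(e$before), length(e$after)) >= fl, logical(1))
    if (sum(keep) < minAnimals) {
      warning(sprintf("floor %d keeps fewer than %d animals; skipped",
                      fl, minAnimals))
      next
    }
    exps <- experiments[keep]
    nMinFl <- min(vapply(exps, function(e)
      min(length(e$before), length(e$after)), numeric(1)))
    ccReal <- ccShuf <- numeric(nBoot)
    for (b in seq_len(nBoot)) {
      eff <- resampleEffect(exps, seed = sample.int(2^31 - 1, 1))
      fr <- fractions[eff$animalId]
      ccReal[b] <- stats::cor(eff$y, fr)
      ccShuf[b] <- stats::cor(sample(eff$y), fr)
    }
    ks <- suppressWarnings(
      stats::ks.test(ccReal, ccShuf, alternative = "less"))
    rows[[length(rows) + 1]] <-
      data.frame(floor = fl, nAnimals = sum(keep), nMin = nMinFl,
                 medianCC = stats::median(ccReal), ksP = ks$p.value)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no floor kept enough animals")
  out$significant <- holmBonferroni(out$ksP, alpha = alpha)
  attr(out, "meanCC") <- mean(out$medianCC)
  out
}

#' Sham effects from non-ablated animals
#'
#' Splits each animal's fixation pool at random into pseudo before/after
#' halves and computes the fractional change in median duration from
#' \code{nMin} fixations per pseudo-condition (no repeats), emulating an
#' ablation that did nothing.
#'
#' @param fixationPools list of per-animal fixation-duration vectors.
#' @param nMin fixations sampled per pseudo-condition (default 33).
#' @param seed integer RNG seed.
#' @return Numeric vector of per-animal sham effects.
#' @export
shamEffects <- function(fixationPools, nMin = 33, seed = 1L) {
  set.seed(as.integer(seed))
  vapply(fixationPools, function(durs) {
    stopifnot(length(durs) >= 2 * nMin)
    idx <- sample(length(durs))
    b <- durs[idx[seq_len(nMin)]]
    a <- durs[idx[nMin + seq_len(nMin)]]
    (stats::median(a) - stats::median(b)) / stats::median(b)
  }, numeric(1))
}

#' Compare targeted ablation groups
#'
#' Repeats the equal-sample resampling \code{nRuns} times; each run
#' produces per-animal effect values for the SR-targeted and
#' control-targeted groups and a one-sided Wilcoxon rank-sum test of
#' whether the SR median effect is larger. Reports the median effect
#' sizes with their min-max across runs and the distribution of rank-sum
#' p-values; when sham effects are supplied, two-sided t tests of each
#' ablated group against sham are Bonferroni corrected.
#'
#' @param srExperiments,controlExperiments experiment-record lists.
#' @param shamEffects optional numeric vector from [shamEffects()].
#' @param nRuns resampling runs (default 100).
#' @param nMin per-repeat sample size (default 33, the single-cell
#'   convention; NULL recomputes it per run from the data).
#' @param seed integer RNG seed.
#' @return A list with per-group effect summaries (median and min-max of
#'   the run means), \code{ranksumP} (min/median/max over runs) and,
#'   when sham data are given, Bonferroni-corrected t-test p-values.
#' @export
compareTargetedGroups <- function(srExperiments, controlExperiments,
                                  shamEffects = NULL, nRuns = 100,
                                  nMin = 33, seed = 1L) {
  stopifnot(length(srExperiments) >= 2, length(controlExperiments) >= 2)
  set.seed(as.integer(seed))
  pvals <- srMeans <- ctrlMeans <- numeric(nRuns)
  warned <- FALSE
  for (r in seq_len(nRuns)) {
    s1 <- sample.int(2^31 - 1, 1)
    s2 <- sample.int(2^31 - 1, 1)
    ySR <- resampleEffect(srExperiments, nMin = nMin, seed = s1)$y
    yC <- resampleEffect(controlExperiments, nMin = nMin, seed = s2)$y
    srMeans[r] <- mean(ySR)
    ctrlMeans[r] <- mean(yC)
    if (length(unique(c(ySR, yC))) == 1) {
      if (!warned) {
        warning("degenerate (all-identical) effects in a run")
        warned <- TRUE
      }
      pvals[r] <- 1
    } else {
      pvals[r] <- suppressWarnings(
        stats::wilcox.test(ySR, yC, alternative = "greater")$p.value)
    }
  }
  out <- list(
    srEffect = c(median = stats::median(srMeans), min = min(srMeans),
                 max = max(srMeans)),
    controlEffect = c(median = stats::median(ctrlMeans),
                      min = min(ctrlMeans), max = max(ctrlMeans)),
    ranksumP = c(min = min(pvals), median = stats::median(pvals),
                 max = max(pvals)))
  if (!is.null(shamEffects)) {
    ySR <- resampleEffect(srExperiments, nMin = nMin, seed = 1L)$y
    yC <- resampleEffect(controlExperiments, nMin = nMin, seed = 2L)$y
    pSR <- stats::t.test(ySR, shamEffects)$p.value
    pC <- stats::t.test(yC, shamEffects)$p.value
    out$shamEffect <- c(median = stats::median(shamEffects),
                        mean = mean(shamEffects))
    out$tTestVsShamP <- stats::p.adjust(c(sr = pSR, control = pC),
                                        method = "bonferroni")
  }
  out
}
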