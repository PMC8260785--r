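#' Normalised fluorescence change (dF/F)
#'
#' (F - mean(F)) / mean(F), with the mean taken over the whole recording.
#'
#' @param F numeric raw fluorescence.
#' @return Numeric dF/F with zero mean.
#' @export
computeDFF <- function(F) {
  f0 <- mean(F, na.rm = TRUE)
  if (!is.finite(f0) || abs(f0) < .Machine$double.eps)
    stop("baseline F0 is zero; cannot normalise")
  (F - f0) / f0
}

#' The fixed saccade-triggered grid
#'
#' 31 bins spanning -5 to +5 s in steps of 1/3 s.
#' @return Numeric vector of length 31.
#' @export
staGridTimes <- function() seq(-5, 5, by = 1/3)

#' Construct an STAProfile from a trial matrix
#'
#' Computes the trial mean and a bootstrap percentile 95\% CI; with
#' \code{nBoot = 0} the CI collapses onto the mean.
#'
#' @param direction \code{"L"} or \code{"R"}.
#' @param trials numeric matrix with 31 columns (one row per trial).
#' @param minTrials minimum rows for eligibility.
#' @param nBoot bootstrap resamples (0 to skip).
#' @return An [STAProfile-class].
#' @export
STAProfile <- function(direction, trials, minTrials = 5, nBoot = 100) {
  grid <- staGridTimes()
  trials <- as.matrix(trials)
  nTrials <- nrow(trials)
  if (nTrials < minTrials)
    return(new("STAProfile", direction = direction, grid = grid,
               trials = trials, mean = numeric(), ciLow = numeric(),
               ciHigh = numeric(), nTrials = as.integer(nTrials),
               eligible = FALSE))
  m <- colMeans(trials)
  if (nBoot > 0) {
    boot <- matrix(NA_real_, nBoot, 31)
    for (b in seq_len(nBoot)) {
      idx <- sample.int(nTrials, nTrials, replace = TRUE)
      boot[b, ] <- colMeans(trials[idx, , drop = FALSE])
    }
    ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975))
    lo <- pmin(ci[1, ], m); hi <- pmax(ci[2, ], m)
  } else {
    lo <- hi <- m
  }
  rownames(trials) <- NULL
  new("STAProfile", direction = direction, grid = grid, trials = trials,
      mean = m, ciLow = lo, ciHigh = hi, nTrials = as.integer(nTrials),
      eligible = TRUE)
}

#' Compute a saccade-triggered average
#'
#' For every saccade of the requested direction that is preceded and
#' followed by a fixation of at least \code{minFixationS} seconds, the
#' chosen signal is linearly interpolated onto the fixed 31-bin grid
#' centred on the saccade. Trials containing missing samples inside the
#' window are dropped. The 95\% confidence interval is a bootstrap
#' percentile interval over trials (\code{nBoot} resamples). Profiles
#' with fewer than \code{minTrials} trials are marked ineligible.
#'
#' @param cell a [CellTrace-class].
#' @param events saccade data frame (\code{onset}, \code{direction}).
#' @param direction \code{"L"} or \code{"R"}.
#' @param signal which trace to average: \code{"dFF"} or
#'   \code{"deconv"}.
#' @param minFixationS minimum flanking fixation duration (s).
#' @param minTrials minimum trials for eligibility (default 5).
#' @param nBoot bootstrap resamples for the CI (default 100).
#' @return An [STAProfile-class].
#' @export
computeSTA <- function(cell, events, direction = c("L", "R"),
                       signal = c("dFF", "deconv"), minFixationS = 5,
                       minTrials = 5, nBoot = 100) {
  direction <- match.arg(direction)
  signal <- match.arg(signal)
  stopifnot(is(cell, "CellTrace"))
  sig <- slot(cell, if (signal == "dFF") "dFF" else "deconv")
  if (!length(sig)) stop("cell lacks the requested signal")
  tt <- traceTime(cell)
  grid <- staGridTimes()

  onsets <- events$onset
  n <- length(onsets)
  qual <- rep(FALSE, n)
  if (n >= 1) {
    pre <- c(Inf, diff(onsets))
    post <- c(diff(onsets), Inf)
    qual <- events$direction == direction & pre >= minFixationS &
      post >= minFixationS & onsets - 5 >= min(tt) &
      onsets + 5 <= max(tt)
  }
  trials <- matrix(numeric(0), nrow = 0, ncol = 31)
  for (s in onsets[qual]) {
    y <- stats::approx(tt, sig, xout = s + grid, rule = 1,
                       ties = "ordered")$y
    if (any(!is.finite(y))) next
    trials <- rbind(trials, y)
  }
  STAProfile(direction, trials, minTrials = minTrials, nBoot = nBoot)
}

#' Holm-Bonferroni step-down rejection
#'
#' Sorts p-values ascending and rejects while
#' \code{p[j] <= alpha / (N - j + 1)}, stopping at the first failure.
#' \code{N} may exceed the number of supplied p-values (comparisons
#' counted but not tested, e.g. ineligible cells).
#'
#' @param pvals numeric p-values in [0, 1] (NA never rejected).
#' @param alpha family-wise error rate.
#' @param N total number of comparisons (default
#'   \code{length(pvals)}).
#' @return Logical rejection mask in the original order.
#' @export
holmBonferroni <- function(pvals, alpha = 0.01, N = length(pvals)) {
  stopifnot(N >= length(pvals))
  reject <- logical(length(pvals))
  ord <- order(pvals, na.last = TRUE)
  for (j in seq_along(ord)) {
    p <- pvals[ord[j]]
    if (is.na(p) || p > alpha / (N - j + 1)) break
    reject[ord[j]] <- TRUE
  }
  reject
}

#' Screen for eye-movement responsive cells
#'
#' Each cell contributes two STA profiles (saccades to the left and
#' right). Cells whose peak absolute STA is in the dataset's bottom 1\%
#' (or below the absolute fallback 0.14 dF/F for small datasets) are
#' dropped before testing. For every remaining profile a one-way ANOVA
#' compares activity across the 31 time bins (bins as groups, trials as
#' replicates). A cell is responsive when either direction's p-value is
#' rejected by [holmBonferroni()] at family-wise \code{alpha} over
#' \code{N = 2 x} (number of cells) comparisons.
#'
#' @param staPairs named list; each element is a list with components
#'   \code{L} and \code{R}, both [STAProfile-class] objects (dF/F based).
#' @param alpha family-wise error rate (default 0.01).
#' @param peakFallback absolute peak threshold used when fewer than
#'   \code{minForQuantile} cells are available.
#' @param minForQuantile dataset size above which the bottom-1\%
#'   quantile replaces the fallback.
#' @return A data frame with one row per cell: \code{cellId},
#'   \code{peak}, \code{tested}, \code{pL}, \code{pR},
#'   \code{responsive}.
#' @export
screenResponsive <- function(staPairs, alpha = 0.01,
                             peakFallback = 0.14,
                             minForQuantile = 100) {
  n <- length(staPairs)
  ids <- names(staPairs) %||% as.character(seq_len(n))
  peak <- vapply(staPairs, function(p) {
    vals <- c(if (isEligible(p$L)) abs(staMean(p$L)),
              if (isEligible(p$R)) abs(staMean(p$R)))
    if (length(vals)) max(vals) else NA_real_
  }, numeric(1))
  thr <- if (sum(is.finite(peak)) >= minForQuantile)
    stats::quantile(peak, 0.01, na.rm = TRUE, names = FALSE)
  else peakFallback
  tested <- is.finite(peak) & peak > thr

  pL <- pR <- rep(NA_real_, n)
  for (i in which(tested)) {
    pr <- staPairs[[i]]
    if (!isEligible(pr$L) || !isEligible(pr$R)) {
      tested[i] <- FALSE
      next
    }
    pL[i] <- .anovaBinsP(staTrials(pr$L))
    pR[i] <- .anovaBinsP(staTrials(pr$R))
    if (is.na(pL[i]) && is.na(pR[i])) {
      warning(sprintf("cell %s: degenerate trials, excluded", ids[i]))
      tested[i] <- FALSE
    }
  }
  allP <- c(pL[tested], pR[tested])
  rej <- holmBonferroni(allP, alpha = alpha, N = 2L * n)
  nt <- sum(tested)
  rejL <- rejR <- logical(n)
  rejL[tested] <- rej[seq_len(nt)]
  rejR[tested] <- rej[nt + seq_len(nt)]
  data.frame(cellId = ids, peak = peak, tested = tested, pL = pL,
             pR = pR, responsive = tested & (rejL | rejR),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' PCA embedding of a population of STAs
#'
#' Each row (one STA) is divided by its L2 norm, the matrix is
#' column-centred, and a principal component analysis is performed. The
#' sign of each component is fixed so its largest-magnitude element is
#' positive, making angles reproducible. Scores on the first three
#' components are scaled to unit rows and converted to spherical
#' coordinates via [sphericalCoords()].
#'
#' @param staMatrix numeric N x 31 matrix of STAs (rows non-zero).
#' @return A [PCAEmbedding-class].
#' @export
pcaEmbed <- function(staMatrix) {
  stopifnot(is.matrix(staMatrix), nrow(staMatrix) >= 4)
  norms <- sqrt(rowSums(staMatrix^2))
  if (any(norms == 0))
    stop("zero row(s) in STA matrix: ",
         paste(which(norms == 0), collapse = ", "))
  fn <- staMatrix / norms
  pc <- stats::prcomp(fn, center = TRUE, scale. = FALSE)
  rot <- pc$rotation
  sco <- pc$x
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  if (ncol(sco) < 3)
    stop("need at least 3 principal components")
  sph <- sphericalCoords(sco[, 1:3, drop = FALSE])
  new("PCAEmbedding", components = unname(rot),
      coefficients = unname(sco), center = as.numeric(pc$center),
      varianceExplained = as.numeric(ve),
      normalizedCoeffs = sph$normalized, phiDeg = sph$phiDeg,
      thetaDeg = sph$thetaDeg)
}

#' Spherical coordinates of three-component coefficients
#'
#' Rows are scaled to unit norm; latitude Theta = asin(c3) (0 at the
#' equator) and longitude Phi = atan2(c2, c1), both in degrees, with Phi
#' in (-180, 180]. The anchor cases are (1,0,0) -> (0, 0),
#' (0,1,0) -> (90, 0) and (0,0,1) -> Theta = 90.
#'
#' @param coeffs3 numeric N x 3 matrix with non-zero rows.
#' @return A list with \code{phiDeg}, \code{thetaDeg} and
#'   \code{normalized} (unit-row matrix).
#' @export
sphericalCoords <- function(coeffs3) {
  stopifnot(is.matrix(coeffs3), ncol(coeffs3) == 3)
  norms <- sqrt(rowSums(coeffs3^2))
  if (any(norms == 0))
    stop("zero row(s): ", paste(which(norms == 0), collapse = ", "))
  cn <- coeffs3 / norms
  theta <- asin(pmin(1, pmax(-1, cn[, 3]))) * 180 / pi
  phi <- atan2(cn[, 2], cn[, 1]) * 180 / pi
  phi[phi <= -180] <- 180
  list(phiDeg = phi, thetaDeg = theta, normalized = unname(cn))
}

#' Population-average STA within a longitude bin
#'
#' Averages the non-normalised STAs whose Phi falls in the half-open
#' angular bin \code{[center - width/2, center + width/2)} (wrapping at
#' +/-180 deg).
#'
#' @param staMatrix numeric N x 31 matrix of raw STAs.
#' @param phiDeg numeric length-N longitudes (degrees).
#' @param center bin centre (degrees).
#' @param width bin width (degrees, default 15).
#' @return A list with \code{mean}, \code{sem} (length-31) and \code{n};
#'   \code{n = 0} with empty profiles when the bin is empty.
#' @export
populationAverageByPhi <- function(staMatrix, phiDeg, center,
                                   width = 15) {
  stopifnot(nrow(staMatrix) == length(phiDeg))
  d <- .angDiff(phiDeg, center)
  sel <- d >= -width / 2 & d < width / 2
  if (!any(sel))
    return(list(mean = numeric(), sem = numeric(), n = 0L))
  sub <- staMatrix[sel, , drop = FALSE]
  list(mean = colMeans(sub),
       sem = apply(sub, 2, stats::sd) / sqrt(nrow(sub)),
       n = sum(sel))
}

#' K-means clustering with silhouette-based selection of k
#'
#' Runs K-means (best of \code{nstart} restarts) for each k in
#' \code{kRange} on the combined normalised coefficient vectors and
#' scores each solution by the mean silhouette width
#' \code{s_i = (b_i - a_i) / max(a_i, b_i)}; the k with the largest mean
#' silhouette is selected.
#'
#' @param x numeric matrix (e.g. N x 6 combined left/right normalised
#'   coefficients).
#' @param kRange candidate cluster counts (default 2:10).
#' @param nstart restarts per k.
#' @param seed integer RNG seed.
#' @return A list of class \code{"ClusterResult"}: \code{k},
#'   \code{labels}, \code{silhouette} (per point, best k),
#'   \code{meanSilhouette} (named by k), \code{centers}.
#' @export
kmeansSelectK <- function(x, kRange = 2:10, nstart = 10, seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) > max(kRange))
  if (nrow(unique(x)) <= max(kRange))
    stop("too many duplicate points for the requested k range")
  set.seed(as.integer(seed))
  dx <- stats::dist(x)
  meanSil <- stats::setNames(rep(NA_real_, length(kRange)),
                             as.character(kRange))
  best <- NULL
  for (k in kRange) {
    km <- stats::kmeans(x, centers = k, nstart = nstart,
                        iter.max = 50)
    sil <- cluster::silhouette(km$cluster, dx)
    ms <- mean(sil[, "sil_width"])
    meanSil[as.character(k)] <- ms
    if (is.null(best) || ms > best$meanSil) {
      best <- list(k = k, labels = km$cluster,
                   silhouette = as.numeric(sil[, "sil_width"]),
                   meanSil = ms, centers = km$centers)
    }
  }
  structure(list(k = best$k, labels = best$labels,
                 silhouette = best$silhouette,
                 meanSilhouette = meanSil, centers = best$centers),
            class = "ClusterResult")
}
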