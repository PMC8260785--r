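test_that("dF/F normalisation matches its definition", {
  expect_equal(computeDFF(rep(4, 10)), rep(0, 10))
  expect_equal(computeDFF(c(1, 3)), c(-0.5, 0.5))
  set.seed(1)
  f <- runif(200, 1, 5)
  expect_equal(mean(computeDFF(f)), 0, tolerance = 1e-12)
  expect_error(computeDFF(c(-1, 1)), "zero")
})

test_that("saccade-triggered averages match archetype templates", {
  # hand-built strictly alternating behaviour, saccades on the sample
  # grid, so the noise-free templates are exact
  n <- 15
  times <- 3 + 8 * (0:(n - 1))
  dirs <- rep_len(c(-1L, 1L), n)
  truth <- list(
    saccadeTimes = times, directions = dirs,
    amplitudes = rep(10, n),
    fixations = data.frame(
      start = times[-n], end = times[-1], duration = diff(times),
      precedingDirection = ifelse(dirs[-n] > 0, "R", "L"),
      followingDirection = ifelse(dirs[-1] > 0, "R", "L"),
      stringsAsFactors = FALSE))
  ev <- truthEvents(truth)
  grid <- staGridTimes()
  for (d in c("L", "R")) {
    bur <- genArchetypeCell("burst", d, truth, sampleRateHz = 1)
    staB <- computeSTA(bur, ev, d, signal = "deconv")
    expect_true(isEligible(staB))
    m <- staMean(staB)
    expect_equal(which.max(abs(m)), 16L)  # t = 0 bin
    expect_equal(unname(m[16]), 1)
    expect_true(all(abs(m[abs(grid) > 1.5]) < 1e-9))
    ton <- genArchetypeCell("tonic", d, truth, sampleRateHz = 1)
    staT <- computeSTA(ton, ev, d, signal = "deconv")
    mT <- staMean(staT)
    expect_true(all(abs(mT[grid < -0.1]) < 1e-9))
    expect_equal(unname(mT[grid > 1.1]),
                 rep(1, sum(grid > 1.1)), tolerance = 1e-9)
    # burst-tonic equals the impulse + step template on the grid
    bt <- genArchetypeCell("burst_tonic", d, truth, sampleRateHz = 1)
    staBT <- computeSTA(bt, ev, d, signal = "deconv")
    expect_equal(staMean(staBT), m + mT, tolerance = 1e-9)
  }
})

test_that("STA trials, eligibility and CIs behave as specified", {
  sim <- fixtureSim()
  ev <- truthEvents(sim$truth)
  cl <- genSRCell(srCellConfig(preferredDirection = "L", seed = 31),
                  sim$truth)
  sta <- computeSTA(cl, ev, "L", signal = "deconv")
  expect_true(isEligible(sta))
  expect_length(staGrid(sta), 31)
  expect_true(all(sta@ciLow <= staMean(sta) + 1e-12))
  expect_true(all(sta@ciHigh >= staMean(sta) - 1e-12))
  # identical trials collapse the bootstrap CI onto the mean
  tri <- matrix(rep(sin(seq(0, 3, length.out = 31)), 6), 6,
                byrow = TRUE)
  p <- STAProfile("L", tri)
  expect_equal(p@ciLow, staMean(p))
  expect_equal(p@ciHigh, staMean(p))
  # too few qualifying trials marks the profile ineligible
  short <- genEyeTrace(behaviorConfig(positionNoiseDeg = 0, seed = 3),
                       fixationDurations = c(8, 8))
  staS <- computeSTA(genArchetypeCell("tonic", "L", short$truth),
                     truthEvents(short$truth), "L", signal = "deconv")
  expect_false(isEligible(staS))
})

test_that("the STA operator is linear over aligned trials", {
  sim <- fixtureSim()
  ev <- truthEvents(sim$truth)
  a <- genSRCell(srCellConfig(preferredDirection = "L", seed = 41),
                 sim$truth)
  b <- genArchetypeCell("tonic", "L", sim$truth)
  combo <- CellTrace(traceTime(a), deconv = 2 * deconv(a) +
                       3 * deconv(b))
  s1 <- staMean(computeSTA(a, ev, "L", signal = "deconv", nBoot = 0))
  s2 <- staMean(computeSTA(b, ev, "L", signal = "deconv", nBoot = 0))
  sC <- staMean(computeSTA(combo, ev, "L", signal = "deconv",
                           nBoot = 0))
  expect_equal(sC, 2 * s1 + 3 * s2, tolerance = 1e-9)
})

test_that("Holm-Bonferroni step-down rejects exactly per its
           thresholds", {
  expect_true(holmBonferroni(0.025, alpha = 0.05, N = 1))
  expect_equal(holmBonferroni(c(0.04, 0.04), alpha = 0.05, N = 2),
               c(FALSE, FALSE))
  expect_true(all(holmBonferroni(rep(0, 5), alpha = 0.01, N = 5)))
  # alpha/(N - j + 1) thresholds: 0.0167, 0.025, 0.05
  expect_true(all(holmBonferroni(c(0.001, 0.02, 0.04), alpha = 0.05,
                                 N = 3)))
  # step-down stops at the first failure even if later p would pass
  expect_equal(holmBonferroni(c(0.04, 0.012), alpha = 0.05, N = 3),
               c(FALSE, TRUE))
  expect_equal(holmBonferroni(c(0.03, 0.02), alpha = 0.05, N = 3),
               c(FALSE, FALSE))
  expect_equal(holmBonferroni(c(NA, 0.001), alpha = 0.01, N = 2),
               c(FALSE, TRUE))
})

test_that("responsive-cell screening detects step responses and honours
           the peak filter", {
  set.seed(7)
  mkPair <- function(step) {
    tmpl <- c(rep(0, 16), rep(step, 15))
    list(L = STAProfile("L", t(replicate(8, tmpl + rnorm(31, 0, 0.1))),
                        nBoot = 0),
         R = STAProfile("R", matrix(rnorm(8 * 31, 0, 0.1), 8),
                        nBoot = 0))
  }
  pairs <- c(lapply(1:30, function(i) mkPair(0.3)),
             lapply(1:10, function(i) mkPair(0)))
  names(pairs) <- paste0("c", seq_along(pairs))
  sc <- screenResponsive(pairs)
  expect_gte(mean(sc$responsive[1:30]), 0.95)
  # cells below the absolute peak fallback are never tested
  tiny <- lapply(1:4, function(i) {
    list(L = STAProfile("L", matrix(rnorm(8 * 31, 0, 0.01), 8),
                        nBoot = 0),
         R = STAProfile("R", matrix(rnorm(8 * 31, 0, 0.01), 8),
                        nBoot = 0))
  })
  names(tiny) <- paste0("t", 1:4)
  scT <- screenResponsive(tiny)
  expect_false(any(scT$tested))
  expect_false(any(scT$responsive))
})

test_that("PCA embedding reconstructs the data and orders variance", {
  set.seed(11)
  t31 <- seq(-5, 5, length.out = 31)
  tmplA <- ifelse(t31 > 0, 1, 0)
  tmplB <- exp(-abs(t31))
  tmplC <- pmax(0, -t31 / 5)
  w <- matrix(runif(90 * 3), 90)
  X <- w %*% rbind(tmplA, tmplB, tmplC) +
    matrix(rnorm(90 * 31, 0, 0.01), 90)
  emb <- pcaEmbed(X)
  ve <- emb@varianceExplained
  expect_true(all(diff(ve) <= 1e-12))
  expect_gte(sum(ve[1:3]), 0.9)
  # full reconstruction of the centred normalised data
  fn <- X / sqrt(rowSums(X^2))
  centred <- sweep(fn, 2, emb@center)
  recon <- emb@coefficients %*% t(emb@components)
  expect_lt(max(abs(recon - centred)) / max(abs(centred)), 1e-8)
  # components are orthonormal
  G <- t(emb@components) %*% emb@components
  expect_equal(G, diag(ncol(emb@components)), tolerance = 1e-9)
  # data varying along one direction on the unit sphere: rank 1 after
  # row normalisation and centring
  theta <- seq(-0.1, 0.1, length.out = 20)
  X1 <- cbind(cos(theta), sin(theta),
              matrix(0, 20, 29))
  expect_gt(pcaEmbed(X1)@varianceExplained[1], 0.999)
  X0 <- X; X0[3, ] <- 0
  expect_error(pcaEmbed(X0), "zero row")
})

test_that("spherical coordinates satisfy the anchor cases and scale
           invariance", {
  anchors <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(-1, 0, 0))
  sph <- sphericalCoords(anchors)
  expect_equal(sph$phiDeg[1:2], c(0, 90))
  expect_equal(sph$thetaDeg[1:3], c(0, 0, 90))
  expect_equal(sph$phiDeg[4], 180)
  set.seed(12)
  cc <- matrix(rnorm(60), 20)
  s1 <- sphericalCoords(cc)
  s2 <- sphericalCoords(2 * cc)
  expect_equal(s1$phiDeg, s2$phiDeg)
  expect_equal(s1$thetaDeg, s2$thetaDeg)
  expect_true(all(abs(rowSums(s1$normalized^2) - 1) < 1e-12))
  expect_error(sphericalCoords(rbind(c(0, 0, 0))), "zero row")
})

test_that("longitude-bin population averages use half-open bins and
           match a brute-force selection", {
  set.seed(13)
  stas <- matrix(rnorm(40 * 31), 40)
  phi <- runif(40, -180, 180)
  phi[1:3] <- 105
  stas[1, ] <- stas[2, ] <- stas[3, ] <- stas[1, ]
  res <- populationAverageByPhi(stas[1:3, , drop = FALSE], phi[1:3],
                                center = 105)
  expect_equal(res$mean, stas[1, ])
  expect_equal(res$n, 3L)
  # boundary membership: 112.5 belongs to the 120 bin, not the 105 bin
  resB <- populationAverageByPhi(rbind(stas[5, ]), 112.5, center = 105)
  expect_equal(resB$n, 0L)
  resC <- populationAverageByPhi(rbind(stas[5, ]), 112.5, center = 120)
  expect_equal(resC$n, 1L)
  # brute-force oracle over the index set
  sel <- phi >= 97.5 & phi < 112.5
  resD <- populationAverageByPhi(stas, phi, center = 105)
  if (any(sel))
    expect_equal(resD$mean, colMeans(stas[sel, , drop = FALSE]))
})

test_that("silhouette-guided K-means recovers the true number of
           clusters", {
  set.seed(14)
  x <- rbind(matrix(rnorm(40 * 6, 0, 0.2), 40),
             matrix(rnorm(40 * 6, 4, 0.2), 40))
  res <- kmeansSelectK(x, seed = 2)
  expect_equal(res$k, 2)
  expect_gt(mean(res$silhouette), 0.7)
  expect_true(all(res$silhouette >= -1 & res$silhouette <= 1))
  # a point midway between the two clusters scores near zero
  xm <- rbind(x, rep(2, 6))
  resM <- kmeansSelectK(xm, kRange = 2, seed = 2)
  expect_lt(abs(resM$silhouette[81]), 0.3)
})
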