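test_that("SR selection finds ramping cells, rejects archetypes, and
           assigns the preferred direction", {
  pop <- fixturePopulation()
  fx <- fixtureSim()$truth$fixations
  sr <- selectSRCells(pop$cells, fx)
  isSR <- pop$kinds == "sr"
  expect_true(all(sr$srFlag[isSR]))
  expect_equal(sr$preferredDirection[isSR], pop$prefs[isSR])
  expect_false(any(sr$srFlag[pop$kinds %in%
                               c("tonic", "burst_tonic")]))
  # monotone noiseless ramps give a rank correlation of exactly 1
  tt <- seq(0, 100, by = 1)
  fx2 <- data.frame(start = c(10, 40, 70), end = c(30, 60, 90),
                    duration = 20,
                    precedingDirection = c("R", "R", "R"),
                    followingDirection = c("L", "L", "L"),
                    stringsAsFactors = FALSE)
  ramp <- numeric(length(tt))
  for (k in 1:3)
    ramp[tt > fx2$start[k] & tt <= fx2$end[k]] <-
      tt[tt > fx2$start[k] & tt <= fx2$end[k]] - fx2$start[k]
  cl <- CellTrace(tt, dFF = ramp, deconv = pmax(ramp, 0))
  out <- selectSRCells(list(cl), fx2)
  expect_equal(out$rhoL, 1)
  expect_true(out$srFlag)
})

test_that("rise times are measured from the threshold crossing and
           normalised by fixation duration", {
  tt <- seq(0, 20, by = 0.5)
  dc <- numeric(length(tt))
  dc[tt > 7] <- (tt[tt > 7] - 7) * 0.5  # onset at t = 7
  cl <- CellTrace(tt, deconv = dc)
  fx <- data.frame(start = 5, end = 15, duration = 10,
                   precedingDirection = "R", followingDirection = "L",
                   stringsAsFactors = FALSE)
  rt <- measureRiseTimes(cl, fx)
  expect_equal(nrow(rt), 1)
  expect_lt(abs(rt$onset - 7), 0.5 + 1e-9)
  expect_equal(rt$riseBeforeSaccadeS + rt$riseAfterPreviousS,
               fx$duration, tolerance = 1e-9)
  # onset 2 s into a 10-s fixation -> normalised rise -0.8
  dc2 <- numeric(length(tt)); dc2[tt >= 7.5] <- 1
  rt2 <- measureRiseTimes(CellTrace(tt, deconv = dc2), fx)
  expect_equal(rt2$normalizedRise, -0.8)
  # sub-threshold activity yields no event
  rt3 <- measureRiseTimes(CellTrace(tt, deconv = rep(0.05,
                                                     length(tt))), fx)
  expect_equal(nrow(rt3), 0)
})

test_that("saccade-locked rise onsets are tighter relative to the
           upcoming than the previous saccade", {
  truth <- fixtureSim()$truth
  cl <- genSRCell(srCellConfig(preferredDirection = "L",
                               riseTimeBeforeS = 5, seed = 60), truth)
  rt <- measureRiseTimes(
    cl, truth$fixations[truth$fixations$followingDirection == "L", ])
  expect_gt(nrow(rt), 20)
  expect_lt(var(rt$riseBeforeSaccadeS), var(rt$riseAfterPreviousS))
})

test_that("slope measurement is exact on lines and filters pure
           noise", {
  tt <- seq(0, 10, by = 0.5)
  cl <- CellTrace(tt, deconv = pmax(0, 2 * tt - 4))
  sl <- measureSlope(cl, 2, 10)
  expect_equal(sl$slope, 2, tolerance = 1e-9)
  expect_equal(sl$fitCC, 1, tolerance = 1e-9)
  expect_equal(sl$valueAtSaccade, 16, tolerance = 1e-9)
  expect_null(measureSlope(cl, 9.6, 10))
  set.seed(3)
  ccs <- replicate(200, {
    cn <- CellTrace(tt, deconv = pmax(0, rnorm(length(tt), 0.5, 0.3)))
    measureSlope(cn, 2, 10)$fitCC
  })
  expect_gt(mean(ccs <= 0.4), 0.4)
})

test_that("slope x rise duration recovers kappa and slopes
           anticorrelate with rise duration", {
  truth <- fixtureSim()$truth
  fx <- truth$fixations
  ev <- do.call(rbind, lapply(1:6, function(i) {
    cl <- genSRCell(srCellConfig(preferredDirection = c("L", "R")[
      1 + i %% 2], noiseSD = 0.02, seed = 70 + i), truth)
    riseEvents(cl, fx, c("L", "R")[1 + i %% 2])
  }))
  expect_gt(nrow(ev), 200)
  prod <- ev$slope * ev$riseBeforeSaccadeS
  expect_lt(abs(median(prod) - 1), 0.05)
  ct <- suppressWarnings(
    cor.test(ev$slope, ev$riseBeforeSaccadeS, method = "spearman",
             alternative = "less"))
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("ROC area matches the brute-force pairwise fraction and its
           limit cases", {
  roc <- saccramp:::.rocArea
  expect_equal(roc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(roc(c(5, 6), c(1, 2)), 1)
  expect_equal(roc(c(1, 2), c(5, 6)), 0)
  set.seed(4)
  for (i in 1:20) {
    sig <- sample(0:5, 7, replace = TRUE)
    noi <- sample(0:5, 9, replace = TRUE)
    brute <- mean(outer(sig, noi, ">") + 0.5 * outer(sig, noi, "=="))
    expect_equal(roc(sig, noi), brute)
  }
  # invariance under strictly monotone transforms (rank-based)
  sig <- rnorm(30); noi <- rnorm(25, 0.5)
  expect_equal(roc(exp(sig), exp(noi)), roc(sig, noi))
})

test_that("choice probability rises toward the saccade and sharpens
           with pooling", {
  truth <- fixtureSim()$truth
  fx <- truth$fixations
  cells <- list(); prefs <- character(0); i <- 0
  for (d in c("L", "R")) for (s in 1:8) {
    i <- i + 1
    cells[[i]] <- genSRCell(srCellConfig(preferredDirection = d,
                                         noiseSD = 0.2,
                                         seed = 200 + i), truth)
    prefs[i] <- d
  }
  cp1 <- choiceProbability(cells, prefs, fx, poolSize = 1)
  expect_true(all(cp1$cp >= 0 & cp1$cp <= 1, na.rm = TRUE))
  near <- cp1$cp[cp1$timeBeforeS <= 1]
  far <- cp1$cp[cp1$timeBeforeS >= 4]
  expect_gt(mean(near, na.rm = TRUE), 0.75)
  expect_gt(mean(near, na.rm = TRUE), mean(far, na.rm = TRUE))
  cp4 <- choiceProbability(cells, prefs, fx, poolSize = 4,
                           nGroupings = 10)
  expect_gt(mean(cp4$cp[cp4$timeBeforeS <= 1], na.rm = TRUE),
            mean(near, na.rm = TRUE) - 0.02)
  expect_true(all(is.finite(cp1$sem[cp1$timeBeforeS <= 2])))
})

test_that("ramp prediction is exact for model-consistent linear
           traces", {
  dt <- 1 / 3
  D <- 2; kappa <- 10  # t_r = 5 s
  y <- D * seq(0, 5, by = dt)
  model <- RampModel(kappa = kappa, derivativeThreshold = 0.5)
  pr <- rampPredict(y, model)
  expect_equal(attr(pr, "onsetIndex"), 1L)
  expect_equal(pr$predictedRemaining + pr$t, rep(5, nrow(pr)),
               tolerance = 1e-9)
  # derivative never above threshold -> no prediction
  expect_null(rampPredict(rep(1, 20), model))
  # non-positive running slope -> NA prediction
  y2 <- c(0, 1, 0.9, 0.2, 0.1, 0)
  pr2 <- rampPredict(y2, RampModel(kappa = 1,
                                   derivativeThreshold = 0.5))
  expect_true(any(is.na(pr2$predictedRemaining)))
})

test_that("ramp model evaluation and its degenerate conventions", {
  x <- c(5, 4, 3, 2, 1)
  ev <- evaluateRampModel(x, x)
  expect_equal(ev$cc, 1)
  expect_equal(ev$timingErrorPct, 0)
  set.seed(5)
  ccs <- replicate(50, {
    a <- runif(40, 1, 10)
    evaluateRampModel(sample(a), a)$cc
  })
  expect_lt(abs(mean(ccs)), 0.1)
  evc <- evaluateRampModel(rep(3, 5), x)
  expect_equal(evc$cc, 0)
  expect_true(evc$degenerate)
  expect_true(is.na(evaluateRampModel(1, 1)$cc))
})

test_that("kappa estimation and saccade-time prediction work across
           fixation durations on a model-consistent population", {
  rp <- fixtureRampPopulation()
  fx <- rp$sim$truth$fixations
  kap <- estimateKappa(rp$cells, rp$prefs, fx)
  expect_lt(abs(kap - 1), 0.05)
  curves <- populationRampCurves(rp$cells, rp$prefs, fx)
  expect_equal(length(curves), 18)
  model <- RampModel(kappa = kap, derivativeThreshold = 0.02)
  pred <- predictSaccadeTimes(curves, model)
  expect_gt(nrow(pred), 200)
  ev <- evaluateRampModel(pred$predictedRemaining,
                          pred$actualRemaining)
  expect_gt(ev$cc, 0.9)
  expect_lt(ev$timingErrorPct, 25)
})

test_that("held-out-cell ramp fits track the population activity", {
  rp <- fixtureRampPopulation()
  fx <- rp$sim$truth$fixations
  res <- rampModelFitCrossCells(rp$cells, rp$prefs, fx,
                                RampModel(kappa = 1,
                                          derivativeThreshold = 0.02),
                                nSplits = 5, seed = 2)
  expect_gt(res$cc, 0.7)
})

test_that("the ideal direction observer scores 1 - pSame analytically
           and empirically", {
  expect_equal(idealObserverDirection(0.23), 0.77)
  expect_equal(idealObserverDirection(0.5), 0.5)
  set.seed(6)
  dirs <- integer(1e5); dirs[1] <- 1L
  same <- runif(1e5 - 1) < 0.23
  for (k in 2:1e5) dirs[k] <- if (same[k - 1]) dirs[k - 1] else
    -dirs[k - 1]
  acc <- empiricalOppositeAccuracy(dirs)
  expect_lt(abs(acc - 0.77), 3 * sqrt(0.77 * 0.23 / 1e5))
})

test_that("the ideal timing observer minimises each cost on the
           conditional distribution", {
  expect_equal(idealObserverTiming(rep(10, 50), 4, "mse"), 6)
  expect_equal(idealObserverTiming(rep(10, 50), 4, "mad"), 6)
  expect_equal(idealObserverTiming(rep(10, 50), 4, "all_or_none",
                                   binS = 0.5), 6.25)
  expect_equal(idealObserverTiming(c(8, 12), 0, "mse"), 10)
  expect_true(is.na(idealObserverTiming(c(8, 12), 15, "mse")))
  # memorylessness: exponential durations give a constant MSE guess
  set.seed(7)
  durs <- rexp(5e4, 1 / 10)
  g <- vapply(c(0, 5, 10), function(e)
    idealObserverTiming(durs, e, "mse"), numeric(1))
  expect_lt(max(abs(g - 10)) / 10, 0.05)
  # degenerate distribution: zero error under the shared metric
  ev <- evaluateIdealObserverTiming(rep(10, 20), cost = "mse")
  expect_equal(ev$timingErrorPct, 0)
})
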