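test_that("a single forced fixation yields exactly two saccades and the
           requested plateau", {
  cfg <- behaviorConfig(positionNoiseDeg = 0, seed = 2)
  sim <- genEyeTrace(cfg, fixationDurations = 10)
  expect_length(sim$truth$saccadeTimes, 2)
  expect_equal(diff(sim$truth$saccadeTimes), 10)
  expect_equal(sim$truth$fixations$duration, 10)
  # the plateau between the two saccades is flat at one level
  tt <- traceTime(sim$trace); pp <- tracePosition(sim$trace)
  mid <- pp[tt > sim$truth$saccadeTimes[1] + 0.5 &
              tt < sim$truth$saccadeTimes[2] - 0.1]
  expect_lt(diff(range(mid)), 1e-9)
})

test_that("direction sequence follows the Markov same-direction
           probability (binomial oracle)", {
  cfg <- behaviorConfig(durationS = 10000, seed = 1)
  sim <- genEyeTrace(cfg)
  dirs <- sim$truth$directions
  n <- length(dirs) - 1
  same <- mean(dirs[-1] == dirs[-length(dirs)])
  se <- sqrt(0.23 * 0.77 / n)
  expect_lt(abs(same - 0.23), 3 * se)
})

test_that("fixation durations reproduce the configured median", {
  cfg <- behaviorConfig(durationS = 50000, seed = 4)
  sim <- genEyeTrace(cfg)
  durs <- sim$truth$fixations$duration
  expect_gt(length(durs), 2000)
  expect_lt(abs(median(durs) - 11.4) / 11.4, 0.05)
  q <- quantile(durs, c(0.01, 0.99))
  expect_true(q[1] > 1.5 && q[1] < 3.5)
  expect_true(q[2] > 40 && q[2] <= 60)
})

test_that("generators are bit-reproducible given config and seed", {
  a <- genEyeTrace(behaviorConfig(durationS = 400, seed = 77))
  b <- genEyeTrace(behaviorConfig(durationS = 400, seed = 77))
  expect_identical(tracePosition(a$trace), tracePosition(b$trace))
  expect_identical(a$truth$saccadeTimes, b$truth$saccadeTimes)
  c1 <- genSRCell(srCellConfig(seed = 3), a$truth)
  c2 <- genSRCell(srCellConfig(seed = 3), b$truth)
  expect_identical(rawF(c1), rawF(c2))
  expect_identical(deconv(c1), deconv(c2))
})

test_that("too-short requested duration fails explicitly", {
  expect_error(genEyeTrace(behaviorConfig(durationS = 2)),
               "too short")
})

test_that("SR ground truth obeys slope x rise duration = kappa and
           rise onsets sit inside their fixation", {
  truth <- fixtureSim()$truth
  cl <- genSRCell(srCellConfig(preferredDirection = "L", seed = 42),
                  truth)
  ev <- cellMetadata(cl)$events
  expect_gt(nrow(ev), 10)
  expect_equal(ev$slope * ev$riseDuration, rep(1, nrow(ev)),
               tolerance = 1e-12)
  expect_equal(ev$deconvAtSaccade, rep(1, nrow(ev)), tolerance = 1e-12)
  fx <- truth$fixations[ev$fixation, ]
  expect_true(all(ev$onset >= fx$start & ev$onset < fx$end))
  expect_true(all(deconv(cl) >= 0))
  # with multiplicative slope noise the product spreads accordingly
  cn <- genSRCell(srCellConfig(preferredDirection = "L",
                               slopeNoiseCV = 0.2, seed = 42), truth)
  evn <- cellMetadata(cn)$events
  ratio <- evn$slope * evn$riseDuration
  expect_gt(sd(ratio), 0.05)
  expect_lt(abs(mean(ratio) - 1), 0.15)
})

test_that("a noise-free ramp with known onset has the exact threshold
           value and slope", {
  cfg <- behaviorConfig(positionNoiseDeg = 0, seed = 6)
  sim <- genEyeTrace(cfg, fixationDurations = c(8, 5, 8))
  pref <- sim$truth$fixations$followingDirection[2]
  cl <- genSRCell(srCellConfig(preferredDirection = pref,
                               riseOnsetFraction = 0.6, seed = 1),
                  sim$truth)
  ev <- cellMetadata(cl)$events
  row <- ev[ev$fixation == 2, ]
  expect_equal(row$riseDuration, 0.4 * 5, tolerance = 1e-9)
  expect_equal(row$slope, 1 / 2, tolerance = 1e-9)
  expect_equal(row$deconvAtSaccade, 1, tolerance = 1e-9)
})

test_that("fluorescence equals the brute-force ramp (x) exponential
           convolution", {
  truth <- fixtureSim()$truth
  cl <- genSRCell(srCellConfig(preferredDirection = "R", seed = 8),
                  truth)
  dec <- deconv(cl)
  tt <- traceTime(cl)
  g <- exp(-median(diff(tt)) / 1.3)
  # direct O(n^2) geometric-sum oracle
  idx <- c(5, 57, 200, length(dec))
  for (i in idx) {
    oracle <- sum(dec[1:i] * g^((i - 1):0))
    expect_equal(rawF(cl)[i], oracle, tolerance = 1e-9)
  }
})

test_that("archetype templates are respected in the deconvolved
           domain", {
  cfg <- behaviorConfig(positionNoiseDeg = 0, seed = 12)
  sim <- genEyeTrace(cfg, fixationDurations = rep(8, 6))
  truth <- sim$truth
  for (d in c("L", "R")) {
    ton <- genArchetypeCell("tonic", d, truth)
    bur <- genArchetypeCell("burst", d, truth)
    bt <- genArchetypeCell("burst_tonic", d, truth)
    tt <- traceTime(ton)
    prefSacc <- truth$saccadeTimes[
      ifelse(truth$directions > 0, "R", "L") == d]
    fx <- truth$fixations
    inPref <- rep(FALSE, length(tt))
    for (k in which(fx$precedingDirection == d))
      inPref <- inPref | (tt > fx$start[k] & tt <= fx$end[k])
    expect_true(all(deconv(ton)[inPref] == 1))
    expect_true(all(deconv(ton)[!inPref] == 0))
    # burst: nonzero only in saccade-containing bins
    nz <- which(deconv(bur) > 0)
    expect_true(all(sapply(tt[nz],
                           function(s) min(abs(prefSacc - s)) < 1.03)))
    expect_equal(sum(deconv(bur) > 0), length(prefSacc))
    # burst-tonic is the sum of the two templates
    expect_equal(deconv(bt), deconv(ton) + deconv(bur))
  }
  expect_error(genArchetypeCell("sustained", "L", truth))
})

test_that("frame stacks translate the base image and honour shift
           limits", {
  base <- genIntensityImage(8, dim = c(48, 48), minSeparationPx = 9,
                            seed = 2)$image
  sh <- rbind(c(0, 0), c(3, -2), c(-5, 7))
  fr <- genFrames(base, sh, noiseSD = 0, seed = 1)
  expect_equal(fr[[1]], base)
  expect_equal(fr[[2]][10, 10], base[10 - 3, 10 + 2])
  expect_error(genFrames(base, rbind(c(30, 0)), seed = 1),
               "half the frame")
})

test_that("intensity images place the requested nuclei or fail
           honestly", {
  blank <- genIntensityImage(0, dim = c(32, 32), noiseSD = 0, seed = 1)
  expect_true(all(blank$image == 0))
  expect_equal(nrow(blank$centers), 0)
  gi <- genIntensityImage(10, dim = c(96, 96), minSeparationPx = 12,
                          seed = 3)
  expect_equal(nrow(gi$centers), 10)
  dmat <- as.matrix(dist(gi$centers))
  expect_true(all(dmat[upper.tri(dmat)] >= 12))
  expect_error(genIntensityImage(200, dim = c(40, 40),
                                 minSeparationPx = 12, seed = 1,
                                 maxTries = 500),
               "could not place")
})

test_that("ground truth round-trips through JSON without loss", {
  sim <- genEyeTrace(behaviorConfig(durationS = 300, seed = 15))
  path <- tempfile(fileext = ".json")
  writeGroundTruth(sim$truth, path)
  back <- readGroundTruth(path)
  expect_equal(back$saccadeTimes, sim$truth$saccadeTimes)
  expect_identical(back$directions, sim$truth$directions)
  expect_equal(back$amplitudes, sim$truth$amplitudes)
  expect_equal(back$fixations, sim$truth$fixations)
})

test_that("eye traces and events round-trip through delimited text", {
  sim <- genEyeTrace(behaviorConfig(durationS = 300, seed = 16))
  p1 <- tempfile(fileext = ".csv")
  writeEyeTrace(sim$trace, p1)
  back <- readEyeTrace(p1)
  expect_equal(traceTime(back), traceTime(sim$trace))
  expect_equal(tracePosition(back), tracePosition(sim$trace))
  ev <- detectSaccades(sim$trace)
  p2 <- tempfile(fileext = ".csv")
  writeSaccadeEvents(ev, p2)
  ev2 <- readSaccadeEvents(p2)
  expect_equal(ev2$onset, ev$onset)
  expect_equal(ev2$direction, ev$direction)
})
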