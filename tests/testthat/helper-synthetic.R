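# shared synthetic fixtures, built once per test run and memoised

.fixtures <- new.env(parent = emptyenv())

# a medium behavioural simulation at the default study conditions
fixtureSim <- function() {
  if (is.null(.fixtures$sim))
    .fixtures$sim <- genEyeTrace(behaviorConfig(durationS = 3000,
                                                seed = 5))
  .fixtures$sim
}

# mixed population: archetype cells + SR cells, realistic noise
fixturePopulation <- function() {
  if (is.null(.fixtures$pop)) {
    truth <- fixtureSim()$truth
    cells <- list(); kinds <- character(0); prefs <- character(0)
    i <- 0
    for (k in c("tonic", "burst", "burst_tonic")) for (d in c("L", "R")) {
      i <- i + 1
      cells[[i]] <- genArchetypeCell(k, d, truth, noiseSD = 0.3,
                                     seed = i)
      kinds[i] <- k; prefs[i] <- d
    }
    for (d in c("L", "R")) for (s in 1:3) {
      i <- i + 1
      cells[[i]] <- genSRCell(srCellConfig(preferredDirection = d,
                                           noiseSD = 0.3,
                                           seed = 100 + i), truth)
      kinds[i] <- "sr"; prefs[i] <- d
    }
    .fixtures$pop <- list(cells = cells, kinds = kinds, prefs = prefs)
  }
  .fixtures$pop
}

# SR-only population on a behaviour stream whose fixation durations are
# exactly the 18 conditioning values (model-consistent ramp testing)
fixtureRampPopulation <- function() {
  if (is.null(.fixtures$ramp)) {
    set.seed(9)
    durs <- sample(rep(seq(3.5, 20.5, by = 1), 6))
    sim <- genEyeTrace(behaviorConfig(seed = 5),
                       fixationDurations = durs)
    cells <- list(); prefs <- character(0); i <- 0
    for (d in c("L", "R")) for (s in 1:8) {
      i <- i + 1
      cells[[i]] <- genSRCell(
        srCellConfig(preferredDirection = d, noiseSD = 0.005,
                     riseOnsetFraction = 0, seed = 100 + i),
        sim$truth)
      prefs[i] <- d
    }
    .fixtures$ramp <- list(sim = sim, cells = cells, prefs = prefs)
  }
  .fixtures$ramp
}

# events data frame straight from ground truth (no detection noise)
truthEvents <- function(truth) {
  data.frame(onset = truth$saccadeTimes,
             direction = ifelse(truth$directions > 0, "R", "L"),
             amplitude = truth$amplitudes,
             stringsAsFactors = FALSE)
}

# build an eye trace with rectangular steps at given times/amplitudes
stepTrace <- function(stepTimes, amplitudes, fs = 13, duration = NULL,
                      noiseSD = 0) {
  duration <- duration %||% (max(stepTimes) + 5)
  tt <- seq(0, duration, by = 1 / fs)
  pos <- numeric(length(tt))
  lev <- 0
  for (k in seq_along(stepTimes)) {
    lev <- lev + amplitudes[k]
    pos[tt >= stepTimes[k]] <- lev
  }
  if (noiseSD > 0) pos <- pos + rnorm(length(pos), 0, noiseSD)
  EyeTrace(tt, pos)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
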