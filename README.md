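# saccramp

Analysis of spontaneous saccadic eye movements and hindbrain calcium
dynamics in larval zebrafish, built around a ramp-to-threshold model of
saccade initiation.

Zebrafish larvae kept in the dark alternate rapid eye movements
(saccades) with seconds-long fixations, with no external trigger. A
subpopulation of hindbrain neurons ("SR" cells) shows activity that
climbs for several seconds before each saccade in a preferred
direction. `saccramp` implements the full analysis chain for asking
whether these cells act as a ramp-to-threshold accumulator: population
activity grows linearly at rate *D* and a saccade fires when it reaches
a fixed bound *κ*, so the time from rise onset to saccade is

&nbsp;&nbsp;&nbsp;&nbsp;*t*<sub>r</sub> = *κ* / *D*,

and a running median of the population derivative yields an online
prediction *κ* / *D̃*(*t*) − *t* of the time until the next saccade.

The package provides, for users analysing eye-tracking plus calcium
imaging data (or validating methods on simulated data):

* **Behaviour** — velocity-threshold saccade detection with a 1.4-s
  artefact rule, fixation segmentation, duration/amplitude statistics,
  Welch power spectra (`detectSaccades`, `segmentFixations`,
  `behaviorSummary`, `positionPowerSpectrum`).
* **Imaging preprocessing** — FFT cross-correlation frame registration,
  median + 5·MAD corrupted-frame flagging, nuclei detection by
  morphological opening + regional maxima with an area filter, 3-D
  affine landmark registration, exponential-decay (τ) fitting
  (`registerFrame`, `flagCorruptedFrames`, `detectNuclei`,
  `fitAffine`, `fitExponentialDecay`).
* **Saccade-triggered analysis** — STAs on a fixed ±5 s, 1/3-s grid
  with bootstrap CIs, ANOVA + Holm–Bonferroni screening of
  eye-movement responsive cells, PCA with a spherical-coordinate
  functional map, silhouette-guided K-means (`computeSTA`,
  `screenResponsive`, `pcaEmbed`, `sphericalCoords`,
  `kmeansSelectK`).
* **SR-cell analysis** — Spearman-based SR selection, rise-time and
  slope measurement, ROC choice probability for direction decoding,
  the ramp-to-threshold saccade-time predictor and ideal-observer
  baselines (`selectSRCells`, `measureRiseTimes`, `measureSlope`,
  `choiceProbability`, `rampPredict`, `idealObserverDirection`,
  `idealObserverTiming`).
* **Ablation statistics** — equal-sample resampled median-effect
  sizes, cylinder-based fraction-ablated estimates, bootstrap
  effect–fraction correlations with shuffle controls, rank-sum group
  comparisons with sham splits (`resampleEffect`, `fractionAblated`,
  `correlateEffectVsFraction`, `compareTargetedGroups`).
* **Synthetic data** — generators for eye traces, SR and archetype
  calcium traces, frame stacks, intensity images and ablation records
  with full ground truth (`genEyeTrace`, `genSRCell`,
  `genArchetypeCell`, `genFrames`, `genIntensityImage`,
  `genAblationExperiments`), so the whole pipeline runs and is tested
  without any download.

## Worked example

Simulate two thousand seconds of behaviour, detect the saccades, build
a small SR population, and run the ramp-to-threshold predictor:

```r
library(saccramp)

sim <- genEyeTrace(behaviorConfig(durationS = 2000, seed = 42))
ev  <- detectSaccades(sim$trace)
fx  <- segmentFixations(ev)
s   <- behaviorSummary(ev, fx)

cells <- list(); prefs <- character(8)
for (i in 1:8) {
  prefs[i] <- c("L", "R")[1 + i %% 2]
  cells[[i]] <- genSRCell(srCellConfig(preferredDirection = prefs[i],
                                       noiseSD = 0.2, seed = i),
                          sim$truth)
}
sr  <- selectSRCells(cells, fx)
kap <- estimateKappa(cells, prefs, fx)
cp  <- choiceProbability(cells, prefs, fx, seed = 1)
curves <- populationRampCurves(cells, prefs, fx)
pred <- predictSaccadeTimes(curves,
                            RampModel(kappa = kap,
                                      derivativeThreshold = 0.02))
res <- evaluateRampModel(pred$predictedRemaining, pred$actualRemaining)
```

This prints (via the corresponding `sprintf` calls):

```
saccades: 140, median fixation: 11.4 s, same-direction: 24.5%
SR cells selected: 8 of 8
estimated threshold kappa: 0.97 (generator: 1)
choice probability 1/3 s before saccade: 0.98
saccade-time prediction: cc = 0.82, timing error = 249% (n = 415)
```

Reading the numbers: the detector recovers the generator's behavioural
statistics (median fixation 11.4 s, roughly a quarter of saccades
repeating the previous direction); all eight synthetic SR cells pass
the Spearman selection; the estimated threshold matches the
generator's κ = 1; activity just before the saccade almost perfectly
decodes its direction (choice probability 0.98 versus 0.5 chance, and
versus 0.77 for an ideal observer using only transition
probabilities); and predicted times-until-saccade correlate with the
actual ones at cc = 0.82. The large median timing error is dominated by
long-horizon predictions made right after rise onset, where the running
slope is still poorly constrained — the error shrinks sharply as the
saccade approaches, and under model-consistent conditions (all rises
spanning their fixation, durations exactly at the conditioning values)
the same code reaches cc > 0.95 with ~10% error; see the methods
vignette (`vignettes/saccramp-methods.Rmd`) for that distinction.

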