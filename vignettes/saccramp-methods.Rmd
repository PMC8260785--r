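---
title: "Methods: spontaneous-saccade analysis and the ramp-to-threshold model"
author: "saccramp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spontaneous-saccade analysis and the ramp-to-threshold model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Larval zebrafish held in the dark spontaneously alternate rapid eye
movements (saccades) with seconds-long stable fixations. Nothing in the
environment triggers these movements, which makes them a tractable model
of self-initiated action. `saccramp` implements an analysis pipeline for
this behaviour and for simultaneously imaged single-cell calcium
activity in the hindbrain, centred on one question: do neurons whose
activity climbs before a saccade (pre-saccadic rise, "SR" cells) behave
like a ramp-to-threshold accumulator whose threshold crossing triggers
the movement?

In the ramp-to-threshold model, a population activity variable grows
linearly at rate $D$ from a rise onset; a saccade occurs when it reaches
a fixed bound $\kappa$, so the time from onset to saccade is
$t_r = \kappa / D$. Reading the running slope off the population trace
therefore yields a prediction of *when* the next saccade will happen,
and the distribution of activity across left- and right-preferring SR
cells predicts *where* it will go.

# The synthetic-data generator

Every stage of the pipeline is exercised on synthetic data with known
ground truth; nothing needs to be downloaded. The generator's defaults
are the study conditions and are not tuned per test.

## Behaviour

`genEyeTrace(behaviorConfig())` simulates eye position at 13 Hz:

* **Direction sequence.** A two-state Markov chain: each saccade repeats
  the previous direction with probability 0.23, otherwise reverses.
* **Fixation durations.** Log-normal, median 11.4 s, log-scale SD 0.69,
  truncated to [1.5, 60] s. The shape parameter was chosen once so the
  1st/99th percentiles land near 2 and 50 s; no single log-normal can
  hit both printed percentiles exactly with this median, so the shape
  splits the difference (realised percentiles ≈ 2.3 and 51 s).
* **Amplitudes.** Reversal saccades aim at a mirrored target
  eccentricity (log-normal, median = half the 13° opposite-direction
  amplitude median), which makes the position walk stationary by
  construction and reproduces the ≈13° reversal median as the sum of the
  current eccentricity and the new target. Same-direction saccades move
  the eye further by a log-normal draw with median 8°, truncated to the
  oculomotor range with a 4° floor. Without the mirrored-target rule the
  position performs an unbounded random walk and piles against any hard
  range limit, producing unrealistically tiny boundary saccades.
* **Why the 4° floor.** The detection threshold
  $\max(\overline{|v|} + 3\,\mathrm{SD}(v),\ 10^\circ/\mathrm{s})$
  self-scales with the saccade content of the trace; at the default
  amplitude statistics it settles near 35–50°/s, i.e. a detection limit
  of roughly 3–4° at 13 Hz. Saccades below that limit are invisible to
  the method being validated, so the generator does not produce them.
  (The detector itself resolves 2° saccades when the trace's amplitude
  range is narrow — see the noise-free recall test.)
* Saccades are rendered as linear position ramps of 0.15 s; Gaussian
  position noise (0.1° SD) is added.

What this does *not* emulate: torsional/vertical movements, tracking
drop-outs, body-movement artefacts in the eye trace, slow post-saccadic
drift, or any dependence of fixation duration on history. Tests passing
on this generator therefore validate the estimators' correctness, not
their robustness to every failure mode of real tracking data.

## Calcium traces

`genSRCell()` builds, for each fixation ending in the cell's preferred
direction, a linear deconvolved-activity ramp that reaches the common
threshold $\kappa$ exactly at the saccade, so ground truth satisfies
slope × rise duration = $\kappa$ per fixation. The rise onset is a
Beta(2, 1.6)-distributed fraction of the fixation, chosen to put the
median rise time near 5 s before the saccade at the default behaviour
statistics while reproducing the broad distribution of
duration-normalised rise times seen in these neurons; the generative law
behind that empirical shape is unknown, and the Beta model is a
stand-in, not a claim. Two alternative onset models support specific
analyses: a fixed onset fraction (`riseOnsetFraction = 0` makes every
rise span the whole fixation) and a saccade-locked onset
(`riseTimeBeforeS`). Fluorescence is the deconvolved trace passed
through the discrete AR(1) form of an exponential calcium kernel with
$\tau = 1.3$ s, plus Gaussian noise. Units are chosen so
$\kappa = 1$; the rise-detection threshold (0.1) applies unchanged on
this scale, and the population derivative threshold is rescaled
proportionally (0.02 per second; the value 35 stored as the
`RampModel` default is the original arbitrary-unit scale).

`genArchetypeCell()` provides the non-SR response classes — tonic
(step for the fixation after a preferred-direction saccade), burst
(impulse in the saccade bin), burst–tonic (both).

A subtlety worth recording: a *noise-free* tonic cell is weakly
rank-correlated with time-to-upcoming-saccade even after the 2-s
post-saccadic exclusion, because the calcium kernel's saturating onset
leaves a small residual rise (about $e^{-2/1.3} \approx 21\%$ of the
step) inside the analysis window. At realistic fluorescence noise the
effect is far below the selection threshold; in the original screen the
very large Holm family played the same suppressing role.

# Behaviour segmentation

`detectSaccades()` median-filters position (0.5-s window, order forced
odd), differentiates, thresholds |velocity| at
$\max(\overline{|v|} + 3\,\mathrm{SD}(v), 10)$ °/s, takes the first
sample of each supra-threshold run as the event time, and discards any
event within 1.4 s of the previously accepted one (short intervals
signal body movements; the *later* crossing is dropped because the first
crossing of a movement is the saccade). `segmentFixations()` tiles the
inter-event intervals; `behaviorSummary()` reports the duration and
amplitude statistics; `positionPowerSpectrum()` is a Welch estimator
(Hann window, half-overlapping segments, linear resampling to the median
sampling interval) that also returns the frequency below which 95% of
non-DC power lies.

# Saccade-triggered analysis

`computeSTA()` linearly interpolates a cell's signal onto the fixed grid
of 31 bins, −5 to +5 s in 1/3-s steps, once per qualifying saccade
(matching direction, flanking fixations ≥ 5 s); trials with any missing
sample in the window are dropped rather than interpolated across gaps.
Confidence intervals are percentile bootstrap over trials (100
resamples). Cells need at least five trials per direction.

`screenResponsive()` runs a classical one-way ANOVA per direction with
the 31 bins as groups and trials as replicates — deliberately the
stated test, ignoring within-trial autocorrelation — and calls a cell
responsive if either direction survives the Holm–Bonferroni step-down
($\alpha = 0.01$, $N = 2\times$ cells). Cells whose peak |STA| falls in
the dataset's bottom 1% are excluded beforehand (absolute fallback 0.14
dF/F for datasets under 100 cells, the original printed cut-off).

`pcaEmbed()` L2-normalises each STA row, centres, and decomposes; each
component's sign is fixed so its largest-magnitude element is positive,
making the angles reproducible across runs. The first three scores are
scaled to unit rows and mapped to longitude/latitude
$\Phi = \operatorname{atan2}(c'_2, c'_1)$, $\Theta = \arcsin(c'_3)$
(degrees; anchors $(1,0,0)\to(0°,0°)$, $(0,1,0)\to(90°,0°)$,
$(0,0,1)\to\Theta=90°$). The two-argument arctangent is required for
the anchor cases to hold in all quadrants. `populationAverageByPhi()`
averages the *raw* STAs in half-open 15° longitude bins;
`kmeansSelectK()` clusters the combined left/right coefficient vectors
for k = 2…10 and selects k by mean silhouette width.

# SR-cell analysis

`selectSRCells()` pools, per direction, strictly pre-saccadic dF/F
samples (excluding the 2 s after the previous saccade, and excluding the
saccade-containing sample itself, which carries the saccadic burst)
against time relative to the upcoming saccade, computes a one-sided
Spearman correlation (large-sample t approximation, average ranks for
ties), and applies the same Holm correction. Cells significant in both
directions are flagged bidirectional and excluded downstream.

Rise timing (`measureRiseTimes()`) takes the last sample before
deconvolved activity exceeds 0.1; slopes (`measureSlope()`) are OLS fits
over [onset, saccade], kept when the fit-to-data correlation exceeds
0.4. The activity value "at the saccade" — used per event and for the
population threshold estimate $\hat\kappa$ (`estimateKappa()`) — is the
regression line evaluated at the saccade time: at ~1 Hz sampling the
saccade falls between frames, and plain interpolation would average the
ramp's last sample with the post-saccadic zero, biasing $\hat\kappa$
low by roughly half a frame's rise. The regression read-out is exact
for noise-free ramps. The same principle restricts all within-fixation
interpolation to samples at or before the fixation end.

`choiceProbability()` compares, at each time before the saccade, the
distribution of interpolated activity preceding preferred-direction
saccades against non-preferred ones using the ROC area (equivalently
the normalised rank-sum statistic; ties count ½). Pooling averages
random disjoint groups of cells sharing a preferred direction, resampled
100 times. The SEM is taken across CPs conditioned on integer fixation
durations 2–20 s (±0.5 s).

# Predicting saccade times

`populationRampCurves()` averages interpolated SR activity aligned to
the upcoming saccade for 18 fixation-duration conditions (3.5–20.5 s,
±0.5 s). `rampPredict()` finds the rise onset as the first
finite-difference derivative above the threshold, estimates the running
slope $\tilde D(t)$ as the median derivative over (0, t], and predicts
the remaining time as $\kappa/\tilde D(t) - t$, reported from one bin
after onset to one bin before the saccade. `evaluateRampModel()` scores
predictions by Pearson correlation and by the **timing error**, defined
here as the median of |predicted − actual| / actual × 100 — a
convention of this package; the original analysis reports a timing-error
percentage without printing its formula.

Two regimes matter when validating the predictor:

* **Model-consistent population** (onsets spanning the whole fixation,
  fixations generated exactly at the 18 conditioning durations, noise
  → 0): the population average is a straight ramp and the predictor
  reaches cc > 0.95 with ~8–10% timing error. This is the regime in
  which the acceptance check asserts cc > 0.9.
* **Default broad-onset population**: rise onsets scattered across the
  fixation make the population average convex, the early running slope
  underestimates the late slope, and cc settles near 0.6–0.8 with large
  early-horizon errors — the same scale the method attains on real
  recordings. This is a property of the running-slope estimator, not of
  the implementation.

The ideal observers provide behaviour-only baselines: always-guess-
opposite direction accuracy $1 - p_{\text{same}}$ (77% at
$p_{\text{same}} = 0.23$), and time guesses minimising MSE / MAD /
all-or-none cost on the conditional remaining-time distribution
(`idealObserverTiming()`), scored with the same timing-error metric.

# Ablation statistics

`resampleEffect()` implements the equal-sample scheme: with
$N_{\min}$ the smallest per-condition fixation count over animals, each
animal contributes $\mathrm{round}(\min_i n_{ij} / N_{\min})$ repeats
(round half away from zero, minimum one — an included animal must
contribute at least one measurement), each drawing $N_{\min}$ durations
per condition without replacement and computing the fractional change in
median duration. With full samples and one repeat this reduces exactly
to (median(after) − median(before)) / median(before).
`fractionAblated()` subsamples the SR map with inclusion probability
3 / (fish count) and intersects an axis-aligned cylinder (30 µm radius,
60 µm along the dorso-ventral axis). `correlateEffectVsFraction()`
repeats the whole resampling at 13 sample-size floors (55–175), compares
100 bootstrap Pearson correlations against shuffled controls with a
one-sided two-sample KS test, Holm-corrected at α = 0.001, and averages
the per-floor median correlations with a plain mean (how the original
aggregated floors with differing animal sets is unstated).
`compareTargetedGroups()` runs 100 resampling rounds of one-sided
Wilcoxon rank-sum tests (SR > control; $N_{\min} = 33$, the single-cell
convention) and, when sham effects are supplied, Bonferroni-corrected
two-sided t tests against them. `shamEffects()` splits non-ablated
animals' fixation pools 50/50 at random (the split ratio is unstated in
the source analysis; 50/50 is implemented).

# Numerical choices and degenerate inputs

* MAD in the corrupted-frame rule is the raw median absolute deviation,
  no 1.4826 consistency factor; the flagging inequality is strict, so
  all-equal errors flag nothing.
* Regional maxima are connected equal-intensity plateaus whose external
  8-neighbourhood is strictly lower; one detection per plateau at its
  centre of mass. Plateaus at or below 25% of the opened image's
  maximum count as background, which keeps the detection count
  invariant to global intensity scaling and returns nothing on blank
  images.
* Registration subtracts image means before the FFT cross-correlation;
  zero-variance frames get error 1. Integer-pixel shifts only — the
  tests need no subpixel refinement.
* The exponential-decay fit fixes the offset to the 1–2 s pre-saccade
  baseline mean and optimises (A, τ) by L-BFGS-B with τ > 0, A ≥ b;
  fits with r² ≤ 0.8 are excluded from the τ aggregate.
* Holm–Bonferroni accepts a comparison count N larger than the number
  of supplied p-values (untested cells still count); NA p-values are
  never rejected and stop the step-down.
* Degenerate cases return flagged values rather than errors where the
  caller can act: constant predictions give cc = 0 with a
  `degenerate` flag; Spearman on constant input gives NA; empty
  longitude bins return n = 0.

# Problem sizes

The test suite and the acceptance script run entirely on synthetic
data: behaviour streams of 3,000–50,000 s (a few hundred to a few
thousand saccades), populations of 6–20 cells, 1,000 null families for
the error-rate calibration, and 100-fold resampling for the ablation
statistics. These sizes give stable estimates for every asserted
quantity while keeping a full run under a minute for the suite and
under half a minute for the acceptance script.

# Known limitations

* The generator's archetypes are caricatures; real tonic/burst cells
  have variable latencies and amplitudes.
* The Spearman selection inherits the calcium kernel's onset transient
  (see above); on extremely clean data it can flag step cells whose
  only "ramp" is the indicator's rise.
* The ANOVA treats interpolated bins as independent groups, as in the
  original analysis; its p-values are anti-conservative with respect to
  within-trial autocorrelation, which the family-wise correction only
  partially offsets.
* CaImAn-style source extraction and deconvolution are out of scope:
  the pipeline consumes deconvolved traces (the generator emits them
  directly) and implements only the forward AR(1) kernel.
* The running-slope predictor's accuracy is bounded by population-level
  linearity, as discussed above; κ transfer across recordings on other
  unit scales requires rescaling the two activity thresholds.
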