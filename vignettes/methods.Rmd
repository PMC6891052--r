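---
title: "Models and methods behind rhythmgain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rhythmgain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`rhythmgain` packages the analysis of how rhythmic temporal expectation
modulates auditory processing: multivariate decoding of tone frequency and
chord identity from multichannel M/EEG, phase-locking analysis around chord
onsets, and a population gain/tuning model that attributes decoding changes
to gain versus tuning-width mechanisms. This vignette explains the models,
the tunable parameters, the synthetic-data generator that stands in for real
recordings, and the numerical and design choices that were genuinely open.

## The stimulus design

Pure tones are drawn from 15 log-spaced carriers spanning two octaves
(460–1840 Hz) with durations 23–43 ms in 5 ms steps, and tiled gaplessly
between chords. Chords comprise six of the fifteen bands: two "common" bands
with identical amplitudes in chords A and B, and four "discriminant" bands,
two louder in each chord, arranged so that the two louder-in-A bands never
both lie above or below the louder-in-B pair (the chords cannot be told
apart by overall pitch). Non-member bands are classed "adjacent" (grid
neighbors of a discriminant band) or "distant". Each trial presents 3–5
short chords and ends with a 165 ms target; in rhythmic blocks every
chord-to-chord interval is 1000 ms, while jittered blocks allocate exactly
50% isochronous intervals, 25% drawn from 570–908 ms, and 25% from
1092–1430 ms (shuffled assignment — the proportions are design facts, not
expectations). Short-chord counts per trial are drawn balanced over
{3, 4, 5}, so a 60-trial block carries exactly 240 short chords, matching
the design counts, and the jittered interval count is divisible by four so
the exact allocation is well defined. The last tone before each chord is
truncated so the fill closes the interval exactly.

The staircase (`staircase_calibrate()`) adjusts the discriminant amplitude
difference with a one-up-two-down rule whose step halves at each reversal
down to a floor of 1% amplitude; the returned level is the mean of the final
reversals. The rule's fixed point is the level where p(correct)² = 0.5,
i.e. ≈ 70.7% accuracy, which the acceptance suite verifies against a
logistic observer.

## The synthetic-data generator

`simulate_recording()` is a deliberately minimal forward model that encodes
exactly the effects the analysis is designed to detect:

* every tone adds a Hanning-shaped response kernel (default peak 76 ms,
  chosen to match the early correlation latency the decoding rests on) with
  a channel topography that varies **linearly with frequency rank** — the
  monotonic frequency code that the encoding analysis tests for;
* every chord adds an identity-specific topography under a later kernel
  (default peak 120 ms);
* a 1 Hz component is phase-locked to chord onsets in rhythmic blocks and
  has a random phase per trial in jittered blocks, with equal amplitude —
  so the conditions differ in phase locking but not in 1 Hz power;
* a multiplicative **gain envelope** scales tone responses as a function of
  their lag to the upcoming chord; condition-specific boosts inside a lag
  window implement "SNR gain at expected moments" at the signal level, and
  the decoding analysis must recover them at the decoding level;
* spatially mixed white Gaussian noise is added (1/f structure is
  deliberately out of scope), and channels of three families (EEG-like,
  magnetometer-like, gradiometer-like) sit interleaved on one quasi-uniform
  spherical-cap lattice so that every channel has neighbors under the
  distance-based adjacency default.

What the generator does **not** emulate: realistic head geometry or leakage
physics, artifacts (blinks, heartbeats), 1/f noise, or latency/amplitude
nonstationarities. Passing recovery tests on this generator therefore shows
that the analysis chain is correct and self-consistent — not that it would
behave identically on real recordings.

Defaults were calibrated once so that desk-scale tone-decoding scores fall
in the plausible range for this kind of data (mean ρ roughly 0.05–0.2):
topography slope 0.25 per rank, noise SD 1, chord amplitude 0.5. Behavioral
accuracies default to 0.72 (rhythmic) and 0.69 (jittered).

## Preprocessing

Continuous data are filtered with fifth-order Butterworth designs at
0.1 Hz (high-pass), 50 Hz and harmonics up to the low-pass corner (notch),
and 200 Hz (low-pass). Zero phase is achieved by applying the squared
magnitude response |H(ω)|² in the frequency domain — exactly the
forward–backward (filtfilt) response without its edge transients; signals
are demeaned before padding so the padding introduces no step edge. EEG
channels are re-referenced to their common average. Epochs are cut at 1 ms
resolution; smoothing uses a centered 20 ms moving average whose window
truncates at epoch edges (length-preserving, no padding artifacts).

Dimensionality reduction follows the encoding analysis: per channel family,
the grand-average channel × time map of Spearman correlations between
per-band mean amplitude and the monotonic frequency contrast is decomposed
by SVD, and the smallest set of modes reaching 95% variance is retained.
The same basis is applied to the continuous single-trial data before
decoding; `apply_basis()` accepts any `component_basis`, so a basis computed
from the continuous data itself can be substituted, but the correlation-map
basis is the default since the decoding is explicitly built on top of the
encoding result. Within the package the basis is computed per simulated
dataset from its own grand-average maps.

## Decoding

For each lag on a −500…+500 ms grid relative to chord onset (only chords
preceded by a 1000 ms interval are used, so the pre-chord stimulus history
is matched across conditions), the tone whose onset–offset span contains
the lag point defines the trial label — tones are gapless, so exactly one
tone is active except while the chord itself plays. Features are component
amplitudes at 26–126 ms after the lag point. In leave-one-out
cross-validation, the held-out trial's Mahalanobis distance to each band's
training mean uses the Ledoit–Wolf shrinkage covariance of all training
trials; the minimum across window offsets is taken independently per
reference band (accommodating frequency-dependent peak latencies), and
distances are averaged across test trials per presented band. The Spearman
correlation of the resulting matrix with the ideal matrix of absolute
carrier differences is the decoding score (a constant matrix scores 0 by
convention). Chord decoding reuses the identical scheme with two classes
and reports other-chord minus same-chord distance over −100…+400 ms.

Two sampling details matter at desk scale and are applied symmetrically:
decoding quality depends on the number of trials, and also on whether a
condition's analysis set is an exhaustive or scattered subset of its
chords, so both conditions are subsampled (seeded) to the same fraction
(default 0.8) of the common eligible minimum. Phase-locking values are
biased upward by 1/√N, so PLV trial counts are equalized by seeded
subsampling before conditions are compared. Both choices are the
desk-scale counterpart of the design's built-in sample equalization (three
rhythmic versus six jittered blocks).

## The gain/tuning model

Distance matrices averaged over the lag window of interest (default
−100…−80 ms) are symmetrized by pooling cells with equal |row − col| and
fitted with

  Z(Δf) = c + g · exp(−Δf² / (2σ²))

by iteratively reweighted least squares (bisquare weights, tuning constant
4.685, convergence at 1e-8 relative change, at most 200 iterations), with
profile points weighted by pooled cell counts. The functional form is a
declared convention: gain `g` scales the depth of the profile uniformly
over Δf, tuning `σ` (in band-index units, since the log-spaced grid is
uniform there) controls how fast distances rise away from the diagonal,
and `c` is the offset. σ is bounded below at half a band (sharper profiles
are unresolvable on the grid) and the parameters are box-constrained to the
data scale, with a breakdown guard that resets the robust weights if they
concentrate on fewer points than parameters + 2 — without these guards the
bisquare loop can chase two points of a noisy 15-point profile to absurd
parameter values. Identifiability is established by recovery, not by
matching any external parameter scale.

Model comparison fits the full model and six reduced models (every proper
subset of parameters free; fixed parameters anchored at the grand-average
fit, which also supplies starting values), computes
AIC = n·ln(RSS/n) + 2k per subject (Gaussian-residual approximation; an
exact fit returns a −∞ sentinel), and enters −AIC/2 as approximate log
evidence into random-effects Bayesian model selection: variational
Dirichlet updates for the expected model probabilities and Monte-Carlo
sampling of the posterior Dirichlet (10⁵ draws, seeded) for exceedance
probabilities.

## Inference

Cluster-based permutation tests form clusters from contiguous same-sign
points exceeding the two-tailed t critical value at α = 0.05 (so the
cluster-forming threshold adapts to the sample size), score them by summed
t, and build the null from sign flips of subject series — full enumeration
of all 2ⁿ flips when n ≤ 12, otherwise 1000 Monte-Carlo flips including
the observed labeling (p ≥ 1/(n+1) and results are seed-reproducible). The
channel × time–frequency variant connects suprathreshold cells adjacent in
frequency or time within a channel and identical cells across neighboring
channels; neighbors are channels within 1.3 × the median nearest-neighbor
distance. The 2 × 4 repeated-measures ANOVA uses the classical per-effect
error strata (df 1,n−1 and 3,3(n−1)); cross-measure correlations z-score
both inputs, and re-estimate after excluding points whose Cook's distance
from the y-on-x regression exceeds the mean. Behavioral d′ and criterion
use identity A as the signal, with the log-linear correction applied at
extreme (0 or 1) rates only, so textbook rates are reproduced exactly.

## Orchestration and problem sizes

`run_config()` carries all seeds (derived from one master seed by a
counter-based split), design constants, ground-truth parameters, and
analysis grids. The shipped defaults are a desk-scale study: 8 virtual
subjects, 1 rhythmic + 2 jittered blocks (the study design's 1:2 ratio) of
12 trials, 80 channels, a 20 ms lag grid. The validation suite uses three
desk-scale settings chosen for statistical adequacy at laptop cost: the
injected-boost recovery runs use 48-trial blocks and a 40-channel array
(the lag of the maximal condition difference is a max statistic, so it
needs the larger trial count); the specificity runs use six-subject null
cohorts with 20-trial blocks (at shorter blocks the desk-scale decoding
scores acquire a small condition asymmetry through the interaction of
trial counts and selection structure — 20-trial blocks were verified
bias-free) and skip the notch filter (the forward model contains no line
noise); and the cluster-test calibration uses 500 null simulations of 20
subjects × 100 samples. Full study-scale settings (22 subjects, 60-trial
blocks, 3 + 6 blocks, 10 ms lag grid, 0.1 Hz PLV grid) are config
overrides, not separate code paths.

## Known limitations

* The forward model's frequency code is strictly linear in rank; quadratic
  encoding exists only as a contrast to test against, never as ground truth.
* The gain/tuning functional form is a convention; alternative
  normalizations of the tuning profile would change parameter scales but
  not the recovery logic.
* The fixed-duration (2000 ms Hanning) analysis window gives
  frequency-independent temporal resolution; a constant-cycle wavelet would
  trade time against frequency resolution differently. The taper is
  switchable.
* Cluster inference controls the family-wise error per test family; the
  pipeline runs several families (decoding, PLV, power) without further
  correction across families, as is conventional.
* At very small trial counts (≲ 2 trials per band) the distance matrices
  are dominated by class-mean noise and decoding scores compress toward
  zero; the desk-scale defaults stay above that regime.
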