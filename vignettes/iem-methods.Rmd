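---
title: "Decoding motion direction with an inverted encoding model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motion direction with an inverted encoding model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iemdecode)
```

## The analysis problem

A participant views random-dot motion whose coherent direction lies between
0° and 90°, preceded on every trial by an auditory cue that predicts one of
two directions (27° or 63°) with 60% validity. Multi-sensor recordings
(e.g. 272 axial gradiometers sampled at 600 Hz) are epoched around stimulus
onset. Separate *localizer* runs present task-irrelevant, fully coherent
motion in 11 directions spanning −45° to 135°; these train a decoder that
is then applied, time point by time point, to the main task. The scientific
questions are (i) whether the decoded direction is pushed toward the cued
direction even though the stimuli are physically identical across cue
conditions, (ii) when in time that push occurs, and (iii) whether it
relates to the behavioral bias the cues induce in perceptual reports.

`iemdecode` implements this analysis end to end, together with a synthetic
data generator that reproduces the experiment's statistical structure, so
the entire pipeline can be exercised and validated without access to any
recordings.

## The inverted encoding model

The decoder is a two-stage *inverted encoding model* (IEM). Stage one
posits `K = 21` hypothetical direction-tuned channels with idealized tuning
curves — a half-wave rectified cosine raised to the sixth power — whose
centres tile the 180° design span from −45° to 135° in steps of
180/21 ≈ 8.57°. A presented direction θ is re-expressed as a vector of
channel amplitudes `c(θ)`, giving the design matrix `C` (channels ×
trials). The forward model

```
B = W C + N
```

maps channel space to sensor space; each row of the weight matrix is
estimated by least squares on the (trial-demeaned) localizer data. The
default estimator regresses the sensors on each channel's predicted
amplitude separately (`fit_mode = "per_channel"`, matching the
channel-by-channel description of the procedure this package follows);
joint multivariate OLS is available as `fit_mode = "joint"`, but note the
21 narrow channels evaluated at only 11 training directions are rank
deficient, so the joint form needs richer designs.

Stage two inverts the model with noise-covariance-aware spatial filters.
For each channel `i`, the residual after removing that channel's own
rank-one prediction, `E_i = B0 − w_i c_i`, yields a sensor covariance
`Σ_i`; it is regularized by analytic (Ledoit–Wolf) shrinkage toward
`ν·I` (`ν` = mean sensor variance) with an intensity computed from the same
residual sample, guaranteeing invertibility even when trials are fewer
than sensors. The filter

```
v_i = Σ_i*⁻¹ w_i   rescaled so that  v_iᵀ w_i = 1
```

returns channel estimates on the scale of the channel activity it
recovers. Applied to test data, `Ĉ = Vᵀ B_test`; the decoded direction per
trial is the argmax over a dense grid (0.1° by default) of the weighted sum
of the basis tuning curves, with ties broken toward the smaller angle and
all-zero estimates flagged as degenerate.

### The tuning-curve period: a genuinely open choice

Two conventions exist for the sinusoid's period. Treating the 180° design
span as one full cycle (`period = "half_circle_doubled"`) makes the
channels tile the span seamlessly, and noise-free decoding is then exact
everywhere — but directions 180° apart become indistinguishable, and the
localizer's endpoints −45° and 135° are *opposite physical motions* that
both occur in training. Keeping the physical 360° period
(`period = "full_circle"`, the package default) separates them, at the
cost of an edge effect: a 135° stimulus lies one channel spacing beyond
the last channel centre (126.43°), and because the readout curve is a
nonnegative mixture of bumps centred at the channel positions, its argmax
is structurally pulled inside the centre range. In noise-free simulations
the 135° direction decodes to ≈ 124.5° (an error slightly above one
spacing) while all interior directions decode within ~3°, and the
11-direction performance correlation still exceeds 0.998. Both conventions
are implemented; the default prioritizes physical identifiability of all
11 training directions. The edge bias is a property of the
weighted-basis-argmax readout itself, not of the fit: it persists at 272
sensors and under every residual/shrinkage variant, and even the ideal
noise-free readout curve for a 135° stimulus peaks at 115.8°.

## Time-resolved decoding

Epochs are baseline-corrected (main task −250–0 ms, localizer −200–0 ms)
and averaged within sliding windows: 28.3 ms wide in 5 ms steps. The width
comes from an a priori 30 ms window reduced by one sample so windows hold
an odd sample count and centre symmetrically — 17 samples at 600 Hz; the
conversion is `round(width × rate / 1000)`, decremented by one if even.
Localizer decoding uses leave-one-run-out cross-validation, training
independently at every window step. Performance is the Pearson correlation
(Spearman optionally) between the 11 presented directions and the mean
decoded direction per presented direction, per time step. Each
participant's individual peak is selected inside the group-level window
(90–110 ms by default, where the group-level decoding first becomes
reliable); the final decoder is trained on the peak step plus two
neighbouring steps on each side, pooled as extra observations and demeaned
once (pooled demeaning was chosen over per-step demeaning; both are
consistent, pooled uses the same means for every training observation).
That one model then decodes every window step of the main task, giving the
time × trials matrix that all statistics consume.

## Statistics

* **Participant QC** — Pearson correlation between the five presented
  directions and the mean reported direction per direction; participants
  below r = 0.9 fail.
* **Perceptual bias** — mean reported direction when 63° was cued minus
  mean when 27° was cued, balanced over presented directions by averaging
  per-(presented × cue) cell means with equal weights. Balancing matters:
  the cued direction occurs at 60%, so raw conditional means would differ
  by part of the 36° cue separation even for a cue-blind observer. Under
  the package's behavioral model (reports = `(1−w)·presented + w·cued` +
  noise) the bias expectation is exactly `36 w`.
* **Cue effect on decoding** — same balanced subtraction applied to the
  decoded direction at every time step.
* **Cluster-based permutation tests** — pointwise one-sample (or
  two-sample) t statistics thresholded at the one-tailed p = 0.05 critical
  value; contiguous supra-threshold steps form clusters scored by summed t;
  the null is the distribution of the maximal cluster mass under random
  participant-wise sign flips (one-sample) or group reassignments
  (two-sample), 10,000 permutations by default, with exhaustive
  enumeration when the flip space is smaller than the requested count. The
  p value includes the observed statistic (`(1 + #{null ≥ obs}) / (1 +
  n_perm)`), so it can never be zero. Cluster effect size `d` is the mean
  over the cluster window of each participant's values, divided by their
  SD. Sign flipping assumes the participant effects are symmetric about
  zero under the null — the standard exchangeability argument for
  within-participant effects.
* **Trialwise partial correlation** — decoded and reported directions are
  residualized on the presented direction (linear covariate by default;
  within-level demeaning via `covariate = "categorical"`), then correlated;
  Fisher's r-to-Z precedes group-level testing.
* **Bias split** — participants partition by the sign of their perceptual
  bias; an exactly zero bias goes to the unbiased group (documented tie
  rule).

## The synthetic-data generator

`ground_truth()` fixes one simulated participant: a sensors × channels
gain matrix with independent standard-normal entries (the generative
counterpart of `W`), an AR(1)-structured spatial noise covariance
(`σ² ρ^|i−j|`, ρ = 0.3 by default) that is white across time, a Gaussian
evoked gain peaking 100 ms post-stimulus (SD 20 ms, zero before onset), an
optional cue-locked *expectation template* — the cued direction's sensor
pattern injected at a chosen amplitude inside a window (135–180 ms by
default) on all cued main-task trials — and a behavioral integration
weight `w`. Designs follow the experiment: localizer blocks of 88 trials
(11 directions × 8, shuffled), main runs with balanced cues and 60/10/10/
10/10 conditional direction probabilities. Reports are a linear mix of
presented and cued directions; as all main-task directions lie between 9°
and 81°, far from the circular wrap, no circular arithmetic is needed.

What the generator does *not* emulate: artifacts, eye movements and
blinks, temporally correlated (1/f) noise, evoked waveform diversity
across sensors beyond a shared gain profile, cue-locked auditory
responses, or between-participant heterogeneity in anything except the
random gain matrix. Passing tests therefore certify the algorithmic
machinery — recovery, calibration, invariances — not robustness to the
full messiness of real recordings.

## Validation design and problem sizes

The validation suite runs at desk scale, with sizes chosen to make each
check statistically meaningful on a single CPU:

* *Noise-free recovery*: 16 sensors, 2 localizer blocks, leave-one-run-out
  at the evoked peak.
* *Trial-starved shrinkage*: 128 sensors with 88 training trials (singular
  raw covariances), 20 replications, analytic shrinkage vs a λ = 0
  pseudo-inverse fallback.
* *Null calibration*: 500 null experiments of 24 participants × 150 time
  steps of exchangeable noise, 1000 permutations each; the family-wise
  false-positive rate must sit inside the 95% binomial interval around
  0.05.
* *Injected-effect detection*: 50 replications of a 24-participant cohort
  (16 sensors, 200 Hz, 2 localizer blocks, 2 main runs of 60 trials,
  readout grid 0.5°). The template amplitude, 0.09, was calibrated once by
  simulation so that the across-participant effect size of the cue-effect
  at a single time point inside the injection window is d ≈ 0.7, and then
  frozen; a significant cluster overlapping 135–180 ms must appear in at
  least 80% of replications.
* *Bias recovery*: `w = 1/36` over ~10⁴ trials against the analytic
  expectation of 1.0°.
* *Oracle equivalences and byte-level determinism* complete the suite.

## Numerical choices and degenerate inputs

Readout grid 0.1° (0.5° in the large simulation loops); ties toward the
smaller angle; all-zero channel estimates return the span midpoint with a
degenerate flag. A channel with zero amplitude variance across training
trials aborts the fit with the channel named. Covariance matrices are
symmetrized after outer products; a singular regularized covariance (only
possible with shrinkage disabled) falls back to a pseudo-inverse. Stage
seeds derive deterministically from one master seed, so every artifact of
a run is a pure function of (configuration, seed); output files embed both
a configuration hash and the seed.

## Known limitations

The edge bias of the full-circle readout (above) is the main structural
caveat; analyses that depend on absolute accuracy at the span edges should
either restrict stimuli to interior directions (as the main task does) or
use the doubled convention and accept 180° aliasing. Joint weight
estimation requires a design of full channel rank, which the standard
11-direction localizer does not provide. The cluster test's sign-flip null
assumes symmetric participant effects. The behavioral model is the
simplest one producing an attractive bias; it makes no claim about the
mechanism generating real reports.
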