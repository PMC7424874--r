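# iemdecode

Time-resolved decoding of continuous motion direction from epoched
multi-sensor neural recordings (MEG-style), built around an inverted
encoding model (IEM), for researchers studying how predictive cues shape
early sensory representations.

## The model

Eleven localizer directions spanning −45°–135° train a forward model

    B = W C + N

where `C` (21 channels × trials) holds the amplitudes of idealized
direction-tuned channels — half-wave rectified sinusoids raised to the
sixth power, spaced every 180/21° — evaluated at each trial's direction,
`B` (sensors × trials) is the demeaned sensor data, and the rows of `W`
come from channel-wise least squares. The model is inverted into
noise-covariance-aware spatial filters: per channel, the residual
covariance `Σᵢ` is regularized by analytic Ledoit–Wolf shrinkage toward a
scaled identity and the filter `vᵢ = Σᵢ*⁻¹wᵢ` is rescaled to unit gain on
its own pattern (`vᵢᵀwᵢ = 1`). Channel responses for unseen data,
`Ĉ = Vᵀ B_test`, are read out as the argmax of the weighted sum of the
tuning curves — a decoded direction per trial, per 28.3 ms / 5 ms sliding
window. Downstream statistics include leave-one-run-out localizer
validation, decoding-peak selection (90–110 ms), the cue-effect
subtraction balanced over presented directions, cluster-based permutation
tests (sum-of-t mass, sign-flip null), perceptual-bias estimation and
trialwise partial correlations between decoded and reported directions.

A synthetic-data module generates ground-truth participants — localizer
and cued main-task designs (two cues, 60% validity), direction-tuned
evoked responses, spatially correlated sensor noise, an optional
cue-locked "expectation template", and behavioral reports biased toward
the cue — so the whole pipeline runs and is validated with no external
data.

## Worked example

Simulate a 12-participant cohort with an expectation template injected at
135–180 ms (amplitude 0.09 ≈ single-time-point d of 0.7) and a behavioral
integration weight of 1/12, decode everyone, and test the cue effect:

```r
library(iemdecode)
pps <- lapply(1:12, function(p) simulate_and_decode(
  seed = 100 + p, template_amplitude = 0.09, cue_weight = 1/12))
ce <- do.call(rbind, lapply(pps, `[[`, "cue_effect"))
cluster_perm_one_sample(ce, times = pps[[1]]$times, n_perm = 2000, seed = 1)
#> Cluster permutation test (one-tailed threshold p = 0.05, 2000 permutations)
#>  start end      mass sign          p         d start_ms end_ms
#>     38  38  1.959305    1 0.98600700 0.5656027     -105   -105
#>     87  91 12.880359    1 0.02998501 0.8343661      140    160
#>     93  94  6.835831    1 0.25987006 1.1541733      170    175
#>     ...
mean(sapply(pps, `[[`, "bias"))
#> [1] 2.53
```

The only cluster surviving the permutation correction (p = 0.030,
d = 0.83) spans 140–160 ms — inside the 135–180 ms injection window: the
decoded direction is pulled toward the cued direction exactly when the
generator placed the expectation signal, and nowhere else. The mean
perceptual bias, 2.53°, sits near its analytic expectation 36 × w = 3°
(positive = reports attracted toward the cued direction).

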