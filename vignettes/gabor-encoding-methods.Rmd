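---
title: "Methods: region-based visual encoding with learnable Gabor convolutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-based visual encoding with learnable Gabor convolutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaborenc)
```

## The encoding problem

A visual encoding model predicts the BOLD response of fMRI voxels in visual
cortex from the stimulus image the subject was viewing. `gaborenc`
implements a lightweight region-based encoder: one network jointly predicts
all voxels of one region of interest (ROI; V1, V2, V3, V4, LO), mapping a
grayscale stimulus through

1. a **Gabor convolutional layer** — 128 kernels (64 "real" cosine-phase and
   64 "imaginary" sine-phase), each 9×9 pixels, stride 2, valid padding,
   ReLU. Each kernel is *synthesized from four scalars* on every forward
   pass: spatial frequency ω (radians/pixel), envelope width σ (pixels),
   phase φ, orientation θ. With rotated coordinates
   x′ = x cos θ + y sin θ, y′ = −x sin θ + y cos θ, the real branch is
   exp(−(x′² + y′²)/(2σ²))·cos(ωx′ + φ), the imaginary branch the sine
   analogue. Because the kernel is an analytic function of (ω, σ, φ, θ),
   gradients flow into those four scalars and the front end stays a Gabor
   family throughout training;
2. two **regular convolutional layers** (64 filters, 3×3, stride 2, valid,
   ReLU);
3. a **squared-weight fully connected map**: r̂ = (w²)ᵀ f + b. Squaring
   makes the effective weights non-negative and gives raw weights the
   self-adapting update Δw ∝ w — features a voxel already relies on are
   tuned faster, which is the selective *feature* optimization.

On a 128×128 input the feature maps are 60 → 29 → 14 per side
(`layer_output_size()`), so the readout sees 14²·64 features per voxel.

Gabor parameters are initialized on a 5-frequency × 8-orientation grid:
θ_n = π(n−1)/8, and ω_m descending from π/2. The printed form of the
frequency ladder is typographically ambiguous in the literature this
follows; we default to the half-octave convention ω_m = (π/2)·2^(−m/2),
m = 0..4 (ratio 1/√2, the usual spacing of Gabor filter banks), and expose
the full-octave alternative ω_m = (π/2)·2^(−m) as
`omega_scheme = "octave"`. With 64 kernels per branch and 40 grid cells,
kernel k wraps deterministically onto cell ((k mod 40) div 8,
(k mod 40) mod 8), so every cell is covered and duplicates occur only where
unavoidable. σ ~ U(0, 5) and φ ~ U(0, π) are drawn per kernel. The Gabor
layer carries a per-channel additive bias (initialized 0); regular
convolution and fully connected raw weights are He-uniform, all other
biases 0.

## Training: selective optimization of features and voxels

Training minimizes, per mini-batch (default 128 stimuli),

Loss = −(1/n) Σ_m ρ_m³ + γ·| (1/n) Σ_m mean(r̂_m) |,

where ρ_m is the within-batch Pearson correlation between predicted and
measured responses of voxel m and n is the ROI's voxel count. The cube is
the product of the accuracy ρ_m with a self-adapting voxel weight ρ_m²:
voxels that are already predictable dominate the gradient (selective *voxel*
optimization), while hopeless voxels are further damped by unit-variance
Gaussian noise added to the predictions during training only
(`inject_noise()`, `noise_sd = 1`). The correlation window is the
mini-batch: the loss must be differentiable per step and no other window is
available at that point. Optimization uses adaptive moment estimation with
base learning rate 0.01 and per-epoch decay lr/(1 + 0.001·(epoch−1)); the
0.001 decay coefficient can alternatively be applied as optimizer weight
decay (`decay_mode = "weight_decay"`). Inside the loss a constant
prediction column contributes ρ = 0 with a warning (degenerate but
trainable); user-facing `pearson_correlation()` raises an error instead.

**The penalty default is γ = 0.** The |grand-mean| term interacts
pathologically with this architecture when optimized by Adam: because the
effective readout weights are squares (non-negative), the penalty's gradient
pushes *every* upstream parameter in the same direction, and Adam's early
steps are sign-normalized, so even γ as small as 10⁻³ drives a uniform
downward drift of the third convolutional layer's weights that silences
every rectifier within one epoch — an absorbing state, since dead ReLUs
pass no gradient. We therefore ship the penalty fully implemented but
default it to 0; on z-scored responses the correlation term alone keeps the
prediction mean bounded. Users who enable γ > 0 should expect to need a
warm-up or plain SGD.

Responses are z-scored per voxel on the training split and the same
transform is applied to validation responses. Unit-variance injected noise
is applied on that z-scored scale. Whether early stopping was used in the
original setting is unstated; we train for a fixed epoch count and report
the full history.

## Significance and model comparison

Per-voxel prediction accuracy is the Pearson correlation between predicted
and measured validation responses (validation repeats averaged first, the
standard treatment for repeated presentations). The significance threshold
comes from a randomization test: permute the sample order of the predicted
matrix, recompute all per-voxel correlations, repeat 1,000 times, and pool
everything into one null distribution; the (1 − α) quantile is a single
global threshold (a per-voxel mode is available). At 120 validation samples
and α = 0.001 this lands near 0.27, matching the analytic t-quantile
r = t/√(t² + n − 2) ≈ 0.279. Exceedance is strict (ρ > threshold).

Two models are compared on the voxels both predict accurately: the observed
fraction won by model A (ties broken by fair coin) is tested against the
(1 − α) quantile of a fair-coin null over the shared voxels. The critical
fraction is computed from the actual shared-voxel count rather than
hard-coded; for counts in the several hundreds it rounds to 53% at
α = 0.05.

## Interpretation: receptive fields and preferred kernels

Guided backpropagation propagates a single voxel's prediction back to the
stimulus; at every rectification the backward signal is masked by (forward
activation > 0) AND (incoming gradient > 0), removing paths that suppress
the response. The package's implementation is verified against an
independent loop-based oracle on randomized tiny networks.

A voxel's receptive field (RF) is estimated from the mean absolute
attribution map over a stimulus set (we use the validation set, mirroring
the use of validation-derived top voxels): the binary RF mask keeps pixels
≥ `mask_fraction` (default 0.1) of the map maximum — the original
binarization rule is undescribed, and 0.1 is the smallest round fraction
that suppresses numerically negligible pixels in pilot simulations; the RF
is summarized by mask area / image area and the attribution-weighted
centroid. Preferred Gabor kernels rank first-layer channels by mean
|gradient × activation| at the Gabor layer output (a pure-gradient score is
config-exposed; the original ranking rule is likewise undescribed). ROI
trends (`roi_trend_summary()`) average these quantities over the top-100
best-predicted voxels per ROI in anatomical order V1…LO and test
monotonicity with the Mann–Kendall statistic S = Σ_{i<j} sign(v_j − v_i),
exact by full enumeration for sequences of length ≤ 8 (one-sided, in the
observed direction), normal approximation with continuity and tie
correction beyond. Note that with only 3 ROIs the smallest attainable exact
one-sided p is 1/6, so sign recovery — not significance — is the meaningful
check at that length.

## The synthetic-data generator

Real stimulus–response data for this task (1,750 training and 120
validation grayscale images, 13 validation repeats) requires a large fMRI
acquisition; the generator emulates its structure at desk scale so that
training, evaluation and interpretation can be exercised with a known
ground truth. Defaults: 400 training / 80 validation stimuli, 32×32 pixels,
20 voxels per ROI, 13 validation repeats, noiseless responses. Each
ground-truth voxel applies one real-branch 9×9 Gabor kernel at a fixed RF
center, to stimulus *contrast* (pixel − 0.5), followed by a positive
readout weight and ReLU. Three profile levels encode the ventral-stream
regularity the interpretation machinery should recover: `low` (σ ∈ [1, 1.8]
px, high ω), `mid` (σ ∈ [2.2, 3]), `high` (σ ∈ [3.4, 5], low ω), with
disjoint envelope ranges. RF centers sit on the stride-aligned grid of the
default architecture and kernels use the model's own 9×9 support, so every
ground-truth rule is *exactly representable* by the model class — parameter
recovery is then a sharp test: `wire_ground_truth_model()` constructs the
exact network (correlation 1 with the generating rule), for which the
attribution machinery recovers RF centroids to within a couple of pixels. What the
generator does **not** emulate: natural-image statistics (stimuli are white
noise, bandpass noise or Gabor-patch mixtures), hemodynamics, measurement
drift, voxel correlations, or the ON–OFF presentation protocol — so passing
recovery tests demonstrates correctness of the machinery, not performance
on real cortical data.

Validation noise is calibrated by test–retest reliability: with noise
variance equal to signal variance, two repeats correlate at 0.5.

## Numerical and design notes

- Convolutions are computed by patch extraction (C++) plus one BLAS matrix
  product; forward/backward passes are exact adjoints (verified by central
  finite differences at step 10⁻⁵ across every parameter group).
- Feature flattening order is row-fastest, then column, then channel
  ("channel-major"), fixed so checkpoints are portable.
- Kernel coordinates: integer grid centered at 0, x rightward, y downward
  (image convention); kernels are re-synthesized from parameters on every
  forward pass; no kernel normalization is applied.
- Degenerate inputs: constant vectors are an error in user-facing
  correlation, ρ = 0 with a warning inside the loss, and flagged/excluded
  voxels in accuracy reports; an all-zero attribution map yields an
  explicit undefined-RF result.
- Ties: `rank_voxels()` breaks accuracy ties by voxel index; dominance ties
  by fair coin from the supplied RNG.
- Problem sizes used in the shipped tests (chosen as desk-scale defaults:
  minutes on one CPU): the generator defaults above for training-based
  checks; 8×8 images with 2 kernels/branch for attribution oracles;
  120 × 600 Gaussian surrogates for the significance threshold.

## Known limitations

- **Channel identifiability.** Training the full model on the default
  noiseless synthetic ROI reliably pushes every voxel's validation accuracy
  above the α = 0.001 permutation threshold and recovers RF centroids, but
  the first layer tends to collapse onto a few broadband large-envelope
  kernels shared across voxels: the squared-weight readout's Δw ∝ w
  dynamics freeze channels whose weights are still small, so the matched
  Gabor kernel often never overtakes an early-winning generalist. The
  preferred-kernel (ω, θ) of a voxel therefore frequently reflects the
  ROI-level compromise rather than that voxel's generating kernel. This is
  a property of the method, not of the implementation — the wired
  ground-truth network shows the attribution machinery itself identifies
  the correct channel when the network uses it.
- The mean-magnitude penalty is unusable with Adam at any tested γ > 0
  (see above).
- Parameter counts grow with ROI size (the 14²·64-feature readout times
  n_voxels); nothing here attempts to stay within any particular budget.
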