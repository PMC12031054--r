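---
title: "Estimating leaf SPAD from RGB images: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating leaf SPAD from RGB images: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`leafspad` inverts leaf color to chlorophyll status (SPAD units) for
single-leaf photographs taken on a bright background under controlled
light. This vignette explains the model at each stage, the tunable
parameters and their defaults, what the synthetic benchmark does and does
not demonstrate, and the design decisions taken where the problem left
genuine freedom.

## Segmentation

A leaf on white paper separates cleanly in HSV space: paper is bright and
achromatic (high value V, low saturation S), leaf pixels are saturated and
darker. A pixel is a foreground candidate when `S >= s_min` (default
0.15, unitless in [0,1]) and `V <= v_max` (default 0.98). An optional hue
gate (e.g. 40–180°, the green range) can be enabled for scenes with
colored clutter; it is off by default because saturation and value
suffice for the intended acquisition setup. Hue is measured in degrees in
[0, 360); users of 8-bit OpenCV conventions (0–179) should halve ours to
compare.

Candidates are grouped into connected components; the largest one wins,
and ties are broken deterministically by the smallest top-left pixel in
row-major order. Holes inside the winning contour are filled before any
color is measured — the region of interest is the filled leaf, not its
boundary. A per-channel median filter (default width 5 px; width 3 is
used in tests because a 3×3 neighborhood is hand-checkable) suppresses
sensor noise inside the ROI only; pixels outside the mask are never
modified. The leaf's color summary is then simply the arithmetic mean of
each RGB channel over the ROI. No learned segmentation, white balancing,
or color-card calibration is attempted.

## Color indices

Twenty-eight indices are computed from the three mean intensities: the raw
channels, pairwise differences and ratios, compound indices such as
(G+B−R)/2G and (2G−R−B)/(2G+R+B), and the normalized chromaticities
r = R/(R+G+B), g, b with their differences. Indices are evaluated on the
ROI *means* (one vector per leaf), not per pixel and then averaged: the
channel means are the measurement, and the algebra operates on scalars.
Zero denominators — unreachable for real leaf colors — yield flagged
missing values with a warning, and such samples are excluded from
correlation and PCA fitting rather than silently imputed.

Column names are compact ASCII renderings of the algebra ("R-B",
"(G+B-R)/(2G)"), used byte-for-byte in every CSV the package writes so
round-trips are loss-free.

## Selection and reduction

Each feature is Pearson-correlated with SPAD. The default selection is a
fixed panel of 21 indices known to track chlorophyll in jujube leaves;
notably the panel is list-based rather than a pure |r| cutoff (it includes
r−b and g−b but not the weakly-correlated r−g), so a `threshold` mode
(default cutoff |r| ≥ 0.7, ordered by |r|) is provided for new crops or
acquisition setups where the panel may not transfer.

The selected features span wildly different scales (raw channels near
100, ratios near 1), so PCA is computed on the **correlation** matrix:
features are standardized with stored means/SDs, the eigendecomposition
is taken, and new data are standardized with the *training* parameters
before projection. Five components are retained by default (a
`variance_target` alternative picks the smallest k reaching a cumulative
explained-variance goal, default 0.9999). Two conventions make scores
byte-stable: each component's largest-magnitude loading is made positive,
and eigenvalue ties break by the original index of the peak loading.

On synthetic data a single latent variable (SPAD) drives all 21 indices,
each through a different nonlinear map; the first component then carries
≈ 98% of the standardized variance and the curvature component nearly all
the rest. One component alone does *not* reach 99% even with zero noise —
a consequence of the feature algebra worth knowing when interpreting
scree plots of this panel.

## Kernel regressors

**SVR.** The ε-insensitive support vector machine minimizes
½‖ω‖² + C Σ(ξᵢ+ξᵢ*) subject to residuals lying within an ε-tube up to
slack. The quadratic program is solved by libsvm (via e1071) at a 1e-7
termination tolerance; tests verify the attained objective against an
independent generic QP solution of the primal. Defaults follow the
configuration used for jujube leaves: linear kernel, C = 0.01, and
ε = 0.1 SPAD units — small against the SPAD SD of ≈ 6. That configuration
also pairs γ = 150 with the linear kernel, where γ has no mathematical
effect; it is stored for
fidelity and an informational message notes its inertness. The degenerate
case where every residual fits in the tube (constant targets) has no
support vectors; the model then predicts the analytic optimum, the
midrange of y.

**RVM.** The relevance vector machine places an individual precision
αᵢ on each kernel-basis weight and maximizes the marginal likelihood over
(α, σ²) — type-II maximum likelihood with the classic simultaneous
fixed-point updates (posterior refresh, αᵢ ← γᵢ/μᵢ², σ² update, pruning
at α > 1e9, convergence when max |Δlog α| < 1e-6). Initialization is
deterministic (αᵢ = 1, σ² = 0.1 var(y)); there is no randomness. The
Gaussian kernel exp(−γ‖x−x′‖²) with γ = 0.01 is the standalone default;
γ = 0.05 is used downstream of the CNN. Predictions carry a variance
σ² + φᵀΣφ, which decays to just above the noise floor far from every
relevance vector.

Two honest caveats, both verified empirically and covered by tests: the
simultaneous update can leave one weakly-weighted extra basis function
per planted source beyond the "three per source" one might hope for
(sequential basis addition would prune harder but is deliberately out of
scope), and with very clean, exactly-representable targets the σ²
estimate can run low, which is the mechanism behind that under-pruning.

## The 1-D CNN and the hybrids

The network treats the 5 principal-component scores as a 1-D,
single-channel sequence. Each block is convolution ("same" padding) →
batch normalization → ReLU → max pooling (window 2, stride 2, skipped
when the map length is below 2). With "same" padding a length-5 input
survives two blocks (5 → 2 → 1); without it the printed 3×1 and 2×1
kernels would be infeasible, which is why padding is fixed rather than
configurable. The standalone network uses one block of sixteen 3-wide
filters; the hybrid feature extractor uses two blocks (3×16, 2×32). The
head is flatten → dense(32) → ReLU → dense(1); head widths are a minimal
choice consistent with "fully connected layers" in the plural.

Training is full-batch Adam on MSE plus an L2 penalty (coefficient 0.001
on convolution/dense weights only), initial learning rate 0.01 stepped
×0.1 every 100 epochs, global gradient-norm clipping at 1.0 (the
post-clip norm is logged every epoch), early stopping on a validation
split with patience 10, and at most 1000 epochs. Full batch removes an
undocumented batch-size hyperparameter; with n ≤ 520 an epoch is
milliseconds. Weights are seeded He-uniform draws, so two runs with one
seed produce identical logs and weights; gradients are verified against
finite differences in the test suite.

The hybrids train in stages: the CNN first, frozen; then the activations
of the `pool2` layer (32 values) for every training row feed an SVR
(CNN-SVR) or a Gaussian RVM with γ = 0.05 (CNN-RVM). The tap is
configurable; `pool2` is used for both hybrids for symmetry. One measured
subtlety: with the study's downstream C = 0.01 the hybrid SVR saturates
around R² ≈ 0.95 on nearly noise-free synthetic data, slightly below a
well-converged CNN; the staged-composition property (the hybrid should
not lose to its own CNN) is therefore exercised in tests with an
adequately-sized downstream (C = 1), while C = 0.01 remains the fidelity
default.

## Evaluation protocol

RMSE and R² follow their standard definitions (R² may be negative and is
undefined for constant truth). The 80/20 split takes a seeded permutation
with |validation| = round(0.2 n); 5-fold cross-validation partitions
samples into equal seeded folds shared by every model. By default the
*entire* preprocessing chain — correlation selection and PCA — is refit
on the training folds of each iteration, so no information from a
validation fold can leak into the features it is scored on; a canary test
shuffles validation SPAD values and checks that training metrics are
bit-identical while validation R² collapses. A `preprocess = "global"`
option reproduces the classical (leaky) fit-once-then-split protocol for
comparison. Reported SDs are over the k folds. The default master seed is
20240625; every random choice in the package flows from an explicit seed
through an RNG-state-preserving wrapper.

## The synthetic benchmark

The generator emulates the acquisition setting: one elliptical leaf
(random eccentricity and rotation, optional midrib stripe — off by
default so the noiseless leaf is perfectly uniform) on a near-white
background (250 ± 3 per channel), 256×256 px by default. SPAD values are
drawn from a normal(42.05, 5.99²) truncated to [21.9, 55.9] by inverse-CDF
sampling — matching the summary statistics of the field campaign this
generator emulates —
and the noise-free leaf color responds linearly to the standardized SPAD
value s̃: (R, G, B) = (90 − 25 s̃, 130 + 10 s̃, 60 + 8 s̃), plus per-pixel
Gaussian noise (SD 4 by default). The signs make red-dominance indices
(R−B) fall and green/blue indices ((G+B−R)/2G) rise with SPAD, matching
the correlation signs reported on real jujube leaves; the linear form is
the simplest monotone model with those signs, and the coefficients are
configurable to probe nonlinearity.

What passing tests show: segmentation recovers the true mask (IoU = 1 up
to boundary pixels), recovered mean colors match the planted ones within
8-bit quantization plus noise averaging, the correlation *signs* and the
low-rank component structure reproduce, and the full pipeline recovers a
planted monotone SPAD–color relationship (validation R² ≥ 0.9 at
per-pixel noise SD 1). What they do not show: field-level accuracy. Real
leaves have venation, specular highlights, shape irregularity, and
illumination drift that the generator deliberately omits; synthetic R²
values near 1 say the code is correct, not that phone photos predict
chlorophyll that well.

## Numerical and degenerate-input policy

Undefined statistics raise typed errors rather than returning NA:
correlation of a constant vector, R² of constant truth, PCA of a
zero-variance column (named in the message), empty ROIs, images with no
foreground after thresholding. RVM posterior inversions fall back from
Cholesky to a graduated-jitter inverse for the rank-deficient designs a
linear kernel produces. All randomness is seed-derived; fold assignments,
split indices, CNN weights, and generator output are byte-reproducible,
and the pipeline writes a resolved-configuration JSON plus a provenance
record (package version, seed, config hash) next to every run's outputs.

## Problem sizes used in the test suite

Unit tests run on small fixtures (tens of samples, 32–128 px images).
The end-to-end checks use the generator's default study conditions — 520
leaves at 256×256 — for the recovery, correlation-structure, and
segmentation-fidelity properties, and 100 seeded leaves for the IoU
sweep. These sizes were chosen as the smallest that exercise the claims
at the study's scale.
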