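---
title: "Sparse mixture-of-experts segmentation of leaf lesions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse mixture-of-experts segmentation of leaf lesions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsemoeseg)
```

## The problem

Lesion segmentation on plant leaves is a binary, pixel-level task: given an
RGB image of foliage, mark the diseased tissue. Disease symptoms are
spatially sparse — most of any leaf is healthy — which motivates two
architectural ideas this package implements end to end:

* **sparse self-attention**, where each query token attends to only a
  retained key set of size $k = \rho n$, reducing attention cost from
  $O(n^2 d)$ to $O(n k d)$ (a $1/\rho$ reduction; $10\times$ at
  $\rho = 0.1$), and
* **mixture-of-experts (MoE) decoding**, where a learned gate routes each
  spatial position to the $k=2$ most appropriate members of a pool of
  heterogeneous convolutional experts, balancing specialization against the
  risk of expert collapse.

Everything runs at configurable scale on a CPU: the networks are built on a
small reverse-mode autodiff tape over dense matrices (`R/ad-tape.R`), with
two compiled gather/scatter kernels (`src/im2col.cpp`) that express
convolutions as matrix products.

## The model

**Encoder.** The image is patch-embedded (stride 4) into $n$ tokens of
width $d$ with learned positions, then processed by pre-norm transformer
blocks whose attention is restricted per query to the top-$k$ keys by
scaled dot-product score. In training mode the selection logits receive
Gumbel noise scaled by a temperature $\tau$ annealed geometrically from 1.0
to 0.1, $\tau_t = \tau_0 (0.1/\tau_0)^{t/T}$; evaluation is strictly
noiseless. Ties break toward the lowest index; $k = \max(1,
\operatorname{round}(\rho n))$. Gradients flow through the retained softmax
weights (hard selection forward, soft weights backward).

**Sparse-enhanced ASPP.** Parallel dilated $3\times3$ branches (reference
rates 1/6/12/18; scaled-down sets for small grids, since a branch whose
effective extent $2r+1$ exceeds the grid is rejected) plus a
global-average-pooling branch are concatenated, normalized and rectified. A
top-$k$ spatial mask scored by channel-mean absolute activation (the
design choice for the unspecified "top-k activation responses") can zero
all but a fraction $\rho$ of positions; it is recomputed each forward pass
rather than tracked by a moving average, since no update rule is
prescribed. A projected spatial attention with content-based top-$k$
neighborhoods fuses the branches, followed by a residual connection and a
squeeze-and-excitation channel gate $s_c = \sigma(W_2\,
\mathrm{relu}(W_1 z))$.

**Dual-stage MoE decoder.** Stage 1 runs four coarse experts — standard
$3\times3$, dilated ($r=6$), depthwise-separable, and a structural replica
of the standard expert with Xavier initialization and single-group
normalization — under top-2 routing by a two-layer gating MLP with
train-time Gaussian logit noise (annealed linearly to zero by the end of
phase 2). The coarse logits are upsampled and fused with a lateral
projection of early encoder features through a per-position sigmoid
integration gate $I_p$: $F^{ref}_p = I_p F^{low}_p + (1 - I_p)
\mathrm{embed}(Y^{(1)}_p)$. Stage 2 concatenates a signed Euclidean
boundary-distance channel (negative inside the thresholded coarse mask;
constant zero when the mask is empty or full, where no boundary exists) and
runs three fine experts — edge-sensitive ($3\times3$ then $1\times1$),
residual, and spatial-attention-gated — again with top-2 routing. A
residual $3\times3$ branch predicts a correction $\Delta Y$, and the head
is $\hat Y = \sigma(Y^{(2)} + \Delta Y)$ upsampled bilinearly
(align-corners false, half-pixel centers) to image resolution. The ladder
is asserted every forward pass: stage 1 at 1/4 scale, stage 2 at 1/2, head
at image scale. The deformable convolution sometimes used for such
residual branches is implemented as a standard $3\times3$ convolution; at
desk scale the geometric flexibility it adds is not testable and the
simpler operator keeps the tape small.

## Losses

The training objective is $L = L_{seg} + \lambda_1 L_{balance} + \lambda_2
L_{sparsity}$ with defaults $\lambda_1 = 0.01$, $\lambda_2 = 0.001$ (an
alternative 0.002 is selectable; both appear in the published recipe and
the configuration resolves the conflict in favor of the tabulated value).
$L_{seg}$ is binary cross-entropy (probabilities clamped at $10^{-7}$)
plus soft Dice with smoothing $\epsilon = 1$. $L_{balance}$ is the
variance of the per-expert soft routing fractions $f_i$ (the printed
normalized-square form is identically equal to the expert count, evidently
a typo, so the variance form is the default and the standard importance
form $M \sum f_i^2 / (\sum f_i)^2$ is the documented fallback).
$L_{sparsity}$ is the mean absolute attention weight per layer — constant
on row-stochastic maps, and carried as printed. The diversity term is
implemented with its printed sign (negated retained-weight entropy), which
*concentrates* attention when minimized; because that contradicts its
stated purpose, a `maximize_diversity` flag exposes the flipped sign, and
the term carries zero weight by default, as does the routing-entropy term.

## Training curriculum

Three phases (defaults 20%/70%/10% of the epochs; the boundaries are not
prescribed, so these were fixed once as round numbers): phase 1 trains the
decoder only with $L_{seg}$, encoder frozen; phase 2 unfreezes everything
under the full objective with cosine learning-rate annealing (encoder
$3\times10^{-4}$, decoder $10^{-3}$, floor $10^{-6}$, linear warmup) and
global gradient clipping at norm 1; phase 3 ramps $\lambda_1$ linearly (to
$5\times$ by default) and drops each expert from the selection with
probability 0.1 before top-k (the dropout rate is unspecified; 0.1 matches
the expert-dropout figure used elsewhere in the recipe), stopping early if
utilization entropy moves less than 0.01 bits over 5 epochs. AdamW weight
decay defaults to $10^{-2}$ with $10^{-4}$ selectable — both values appear
in the recipe. All noise streams (shuffling, Gumbel, gate noise,
augmentation) derive from one seed; two runs with the same inputs produce
identical loss curves. Within the training loop the learning-rate schedule
is evaluated at the epoch midpoint ($t = e - 1/2$), so the first warmup
epoch trains at half the peak rate rather than at the zero the left
endpoint would give; the schedule functions themselves keep their exact
endpoint anchors.

## The synthetic scene generator

No external imagery is used anywhere. Scenes are superellipse leaves
(random axes, rotation, exponent 2–3, green with per-leaf jitter) over
soil-toned clutter, occluding each other in painter's order. Lesions are
radial Gaussian intensity profiles with half-maximum radius drawn from
$N(\mu, \sigma^2)$, blended toward a necrotic brown, placed uniformly over
the positions where the half-maximum disk fits inside the leaf (uniform
placement is the stand-in for "randomized biologically plausible
locations", which no source specifies further); a configuration whose
lesions cannot be placed within 100 attempts is rejected. The binary mask
is the union of half-maximum supports restricted to the visible part of
each leaf, so every mask pixel lies inside an instance support. Occlusion
is controlled by bisection on a radial spread factor until the occlusion
complexity $\kappa$ — the mean fraction of each instance covered by the
union of the others — is within $\pm 0.05$ of target.

Default study conditions, fixed once: $64\times64$ scenes, 2 leaves, 2
lesions per leaf, radius $8 \pm 2$ px, occlusion target 0.15, clutter
0.25. These were chosen as a realistic desk-scale rendering of moderately
diseased, partially occluding foliage. What the generator does *not*
emulate — photorealistic texture, species-specific venation, specular
lighting, true field backgrounds — bounds what passing tests show: they
validate the architecture, optimization and statistics machinery, not
field-readiness on real crops.

Low-light robustness experiments use multiplicative brightness factors
(reference points 0.7/0.5/0.3) plus Gaussian sensor noise ($\sigma =
0.05$); augmentation follows the published recipe (flips at 0.5, rotation
$\pm15°$ by default with $\pm30°$ selectable — both appear in the recipe
and the configuration wins — scaling 0.8–1.2, brightness/contrast jitter
0.2, saturation 0.1, noise $\sigma = 0.01$ at probability 0.3).

## Quality control and metrics

The QC module reports class entropy (base-2 throughout; the base is
printed inconsistently at the source, but only base 2 reproduces the
published 38-class entropy), occlusion complexity, Cohen's kappa with the
0.85 acceptance gate, the 256-bin image-entropy filter with its 2.0-bit
discard rule, Jensen–Shannon divergence, GLCM texture statistics (4-level
quantization, one offset at distance 1, angle 0° — no parameters are
prescribed), mean pairwise global SSIM per class (reported, not gated —
no threshold is stated), and 8×8 average-hash duplicate detection.
Segmentation quality uses IoU, Dice, precision, recall (both-empty masks
score 1, exactly one empty scores 0) and the boundary Hausdorff distance
in pixels (no pixel-to-physical calibration is available, so physical
units are not reported), with boundaries extracted by 4-connectivity.

## Numerical choices and scale

Tolerances: sparse-vs-dense attention equivalence is asserted at $10^{-6}$
over 100 fuzz cases; the masked-dense oracle matches the restricted
softmax at $10^{-12}$ in eval mode; metric and loss identities are exact.
Degenerate inputs are defined explicitly: empty masks in metrics, empty or
full masks in the distance transform, all-zero class counts and
non-normalized distributions are errors.

The test-suite benchmark trains the default desk-scale model — $64\times64$
inputs, width 32, depth 2, two heads, $\rho = 0.25$ (256-token sequences
make the reference $\rho = 0.1$ needlessly aggressive), ASPP rates 1/2/4/6
on the $16\times16$ grid, 4+3 experts with top-2 routing — for 5 epochs on
200 generated scenes with minibatches of 2 (small batches buy more
optimizer updates within the short epoch budget), evaluating on 30
held-out scenes.
These sizes are the package's chosen benchmark conditions: large enough to
exercise every module and demonstrate learning, small enough to run
routinely as part of the suite.

## Known limitations

* Single-image (batch-free) tensor layout: minibatches are accumulated by
  looping samples, which is simple and exactly reproducible but leaves
  BLAS-level batching on the table.
* The normalization layers compute per-image statistics (instance-style)
  rather than cross-batch batch-norm moments; with batch accumulation this
  is the natural choice, and the freeze rule after phase 1 therefore has
  nothing to freeze by default.
* Binary masks only; the multi-class labels in the generator metadata
  serve stratification and QC, not a multi-class head.
* The Hausdorff distance is reported in pixels, not physical units.
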