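# sparsemoeseg

Sparse mixture-of-experts semantic segmentation of plant leaf lesions, at
configurable desk scale, fully testable without external data.

Plant disease symptoms are spatially sparse: most of a leaf is healthy
tissue, and dense self-attention spends quadratic compute mostly relating
healthy pixels to each other. This package implements, in R, a
segmentation framework built around that observation, for researchers in
quantitative plant pathology and biological image analysis who want an
inspectable, CPU-scale implementation of its components:

* **Gumbel-TopK sparse self-attention** — each query attends only to its
  top `k = ρ·n` keys by scaled dot-product score, cutting attention cost
  from `O(n²d)` to `O(nkd)`, a `1/ρ` reduction (10× at ρ = 0.1). Training
  perturbs the selection logits with temperature-annealed Gumbel noise
  (`τ_t = τ0·(0.1/τ0)^(t/T)`); evaluation is noiseless, with a dense
  oracle for equivalence testing.
* **Mixture-of-experts decoding in two stages** — four coarse experts
  (standard, dilated, depthwise-separable, replica) then three fine
  experts (edge-sensitive, residual, spatial-attention), each position
  routed to its top-2 experts by a gating MLP:
  `Y_p = Σ_{i∈J_p} α̃_{p,i} f_i(F_p)`, with load-balancing
  (`L_balance = (1/E)Σ(f_i − f̄)²`) and entropy regularizers plus
  utilization statistics (entropy, Gini, collapse detection).
* **Sparse-enhanced ASPP** — parallel dilated branches with a pooling
  branch, top-k spatial masking, content-based sparse attention fusion,
  and squeeze-and-excitation recalibration.
* **Composite loss** — `L = L_seg + λ1·L_balance + λ2·L_sparsity` with
  `L_seg` = BCE + soft Dice, defaults λ1 = 0.01, λ2 = 0.001.
* **Dataset QC and metrics** — class entropy, occlusion complexity κ,
  Cohen's kappa (0.85 gate), image-entropy filtering (2-bit rule),
  Jensen–Shannon divergence, GLCM/SSIM/perceptual-hash screening; IoU,
  Dice, precision/recall, boundary Hausdorff distance, FLOPs and runtime
  accounting.
* **A synthetic leaf-lesion scene generator** — superellipse leaves with
  Gaussian-profile lesions, controllable occlusion and low-light
  degradation — so the entire pipeline trains and evaluates end to end on
  generated data.

Networks are trained with a small built-in reverse-mode autodiff engine
(dense-matrix tape plus two compiled gather/scatter kernels); no external
deep-learning framework is required. The three-phase curriculum (frozen
encoder warm start, full fine-tuning under cosine annealing, balance-ramp
specialization) and every published hyperparameter default live in
`inst/config/default.yaml`.

## Worked example

```r
library(sparsemoeseg)

# a 64x64 scene: two occluding leaves, two lesions each, radius 8 +/- 2 px
cfg <- scene_config(n_leaves = 2, n_lesions = 2, lesion_mu = 8,
                    occlusion_target = 0.15, seed = 11)
scene <- generate_scene(cfg)
sum(scene$mask)                       # 569 lesion pixels (13.9% of image)
scene$metadata$kappa                  # 0.172: achieved occlusion complexity

image_entropy_filter(scene$image)     # 4.53 bits -> keep (>= 2.0 rule)

# analytic sparse-attention accounting at the reference sparsity
complexity_report(n = 4096, d = 256, k = 410)$reduction_factor  # 10

# forward pass of the desk-scale model (untrained weights)
model <- build_model(model_config(rho = 0.25, seed = 1))
fw <- forward(scene$image, model)
fw$aux$observed_attention_sparsity    # 0.75, exactly 1 - k/n in eval mode
segmentation_metrics((fw$y_hat >= 0.5) * 1L, scene$mask)$iou  # 0.012

# train it: the benchmark used by the test suite (about 7 minutes)
bm <- run_tiny_benchmark(seed = 1)
bm$eval$mean_iou                      # 0.815 on 30 held-out scenes
bm$utilization_entropy                # 1.89 bits across 4 experts
```

The numbers above are what the code printed for these calls: an untrained
model segments at chance (IoU 0.012), and five epochs on 200 synthetic
scenes lift held-out IoU to about 0.81 while expert utilization stays near
the 2-bit maximum (no collapse).

A thin command-line wrapper over the same functions ships in
`inst/cli/sparsemoeseg` with subcommands `simulate`, `qc`, `train`,
`eval`, `profile`.

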