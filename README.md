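# odadetect

Occlusion- and density-aware detection blocks for small-fruit imagery, in
pure R.

Detecting ripening coffee cherries in orchard photographs is hard for
standard one-stage detectors: the fruits are small (usually under 32×32 px
at 640×640 resolution), frequently hidden behind leaves, and packed into
tight clusters along fruit-bearing branches. `odadetect` implements the
three architectural mechanisms that target exactly these failure modes,
together with everything needed to exercise them end-to-end on CPU without
a GPU framework or an external dataset:

- **Condition-Guided Windowed Attention (CGWA)** — multi-head
  self-attention inside non-overlapping `Ws × Ws` windows with a learned
  relative-position bias `B`, modulated by two guidance rasters. Per window
  and head,

  `A = softmax( α(O, D) · (Q Kᵀ / √d_k) + B + β(O, D) ) V`

  where `O` and `D` are occlusion and density condition maps pooled to the
  feature resolution, `α(·) ∈ (0,1)` is a per-head modulation predicted by
  a small MLP from window-mean conditions, and `β(·) ∈ (0,1)` is an
  additive key-side boundary bias from a small conv net. The score tensor
  has `Ws⁴ · (H/Ws) · (W/Ws)` entries per head instead of `(HW)²`.
- **Attention-guided Space-Preserving Convolution (ASPC)** — downsampling
  that discards nothing: a bijective space-to-depth rearrangement
  (`B×C×H×W → B×4C×H/2×W/2`), a 3×3 convolution, then cascaded attention
  `F_out = M_ch ⊙ (M_sp ⊙ Conv₃ₓ₃(SPD(F_in)))` with
  `M_sp = σ(Conv₇ₓ₇([mean_c(F); max_c(F)]))` and
  `M_ch = σ(MLP(avgpool F) + MLP(maxpool F))`.
- **Dual-Adaptive Dynamic Upsampling (DADU)** — content-adaptive
  upsampling: a 1×1 and a 3×3 convolution each predict sampling offsets
  `Δ₁, Δ₂` of shape `B×2Gs²×H×W`; a learnable scalar fuses them convexly,
  `Δ = σ(α)Δ₁ + (1−σ(α))Δ₂`; the output is group-wise bilinear grid
  sampling at `P_base + Δ` with border padding (optional pixel-shuffle
  pre-expansion and a dynamic-scope contraction are supported).

Around the blocks the package provides: adaptive-Gaussian **density maps**
(`σᵢ = clamp(β·d̄ᵢ, σ_min, σ_max)` from the mean distance to the k nearest
fruit centers), image-derived **occlusion maps** (local contrast
attenuation + Sobel edge discontinuity), an HSV/RGB **colorimetric
ripeness classifier** (unripe / semi-ripe / ripe), a deterministic
**synthetic orchard generator** with exact per-fruit occlusion fractions
and YOLO-format labels, and a reduced-width **detector assembly** with
training, mAP@0.5 / precision / recall / F1 evaluation, a confusion matrix
with background row/column, parameter/GFLOP accounting and Grad-CAM-style
heatmaps. All neural blocks run on a small reverse-mode autodiff tape
written in base R, so the package trains models with no external deep
learning dependency.

## Worked example

```r
library(odadetect)

# a deterministic 640x640 orchard scene in the default study regime
sc <- render_scene(scene_spec(seed = 7))
nrow(sc$truth$boxes)                       # 30 fruits
mean(sc$truth$occluded_fraction > 0.3)     # 0.3 in this scene (~0.4 over many)

# condition maps from the image and its annotations
cond <- condition_pair(sc$image, sc$truth$boxes)
range(cond$density)                        # [0, 1)

# colorimetric round trip for an unoccluded fruit
i <- which(sc$truth$occluded_fraction == 0)[1]
classify_box(sc$image, sc$truth$boxes[i, ])
#> $class     "ripe"      (matches sc$truth$class[i])
#> $fraction  1

# a tiny full detector: train 30 steps on four 64x64 scenes
scenes <- lapply(1:4, function(s) render_scene(scene_spec(
  image_size = 64, n_fruits = 3, radius_range = c(5, 8),
  occluder_density = 0, cluster_fraction = 0,
  background_texture = "flat", seed = s)))
m <- assemble(model_config(base_channels = 4, input_size = 64,
                           window_size = 4, heads = 2), seed = 1)
tr <- train_tiny(m, scenes, steps = 30, seed = 2)
round(tr$loss_trace[c(1, 30)], 2)          # 11.69 -> 6.39
```

The loss components are balanced objectness BCE, per-class BCE and L1 box
regression in cell units, plus an auxiliary MSE for the predicted-density
head; after 200 steps on eight such scenes the full assembly reaches
mAP@0.5 = 1.0 on its training set (see the acceptance script below).

Thin command-line wrappers over the same functions live in `inst/cli/`
(`condmaps.R`, `generate.R`, `classify-color.R`, `train-tiny.R`,
`eval.R`).

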