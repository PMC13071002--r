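---
title: "Occlusion- and density-aware detection blocks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occlusion- and density-aware detection blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(odadetect)
```

# The problem

Small-fruit detection in orchard imagery fails in characteristic ways.
Fruits under 32×32 px lose their activations after a couple of stride-2
downsamples (each conventional downsample discards about 75% of spatial
positions); fruits behind foliage produce weak, diffused responses; and
tightly clustered fruits get merged into single detections during feature
upsampling. The three blocks in this package target those failure modes
directly, and the rest of the package exists so that each mechanism can be
exercised and verified end-to-end on a CPU, without field data.

# Models

## Condition maps

The attention block is conditioned on two single-channel rasters in
\[0, 1\] at image resolution.

**Density** (`generate_density_map`): one isotropic Gaussian kernel per
annotated fruit center, summed and divided by the raster maximum plus a
`1e-6` guard so values lie in \[0, 1). Kernels are geometry-adaptive, as
in crowd-counting practice: `sigma_i = clamp(beta * dbar_i, sigma_min,
sigma_max)`, where `dbar_i` is the mean center distance to the `k`
nearest fruits. Defaults `k = 3`, `beta = 0.3`, `sigma_min = 1` px,
`sigma_max = 15` px are the crowd-counting convention; the adaptive
principle fixes only the form, not the constants. Each kernel is
normalised to unit discrete integral (truncated at 4 sigma, so the
integral is within a fraction of a percent of 1 for sigma up to ~8 px).
Coordinates are 0-based with pixel centers at index + 0.5; a box center
at exactly 0.5 therefore sits midway between two pixel centers and the
argmax tie resolves to whichever the floating-point evaluation favours —
tests accept either neighbour.

**Occlusion** (`generate_occlusion_map`): the average of a
contrast-attenuation term `1 - s_local/(s_global + eps)` (grayscale
standard deviation in a 7×7 window against the whole image) and a
normalised Sobel gradient magnitude, clipped to \[0, 1\]. Both terms are
ratios, so the map is invariant to global affine brightness changes; an
image with near-zero global contrast returns all zeros. The 50/50 mix,
the 7×7 window and Sobel gradients are this module's canonical
definition of "local contrast attenuation and edge discontinuity
analysis". No annotations are needed, so occlusion maps are available at
inference time.

`pool_condition` resizes either raster to a feature scale by exact
fractional area averaging (each target cell is the overlap-weighted mean
of the source cells it covers), so constant rasters stay constant and
values never leave the input range.

## Condition-guided windowed attention

Within each non-overlapping `Ws × Ws` window (default `Ws = 7`; the grid
is zero-padded and padded cells are masked with −∞ logits):

```
A = softmax( alpha_h(O, D) * (Q K^T / sqrt(d_k)) + B + beta(O, D) ) V
```

- The relative-position bias table has `(2 Ws − 1)²` learnable rows per
  head, indexed by the query–key displacement only, giving translation
  equivariance inside the window.
- `alpha_h` is produced by a two-layer MLP (ReLU, optional dropout,
  sigmoid) from the window's mean occlusion and density; it multiplies
  the *scaled* logits, after the `1/sqrt(d_k)` division. Because the
  sigmoid keeps it strictly inside (0, 1) there is no neutral setting;
  equivalence tests freeze the factor at a known constant instead.
- `beta` is a single-channel map from a two-layer conv net over the
  concatenated rasters, added at each *key* position (broadcast over
  queries and heads) so that condition boundaries attract attention.
- Both the modulation MLP and the boundary net consume rasters refined by
  two parallel lightweight three-layer conv encoders (widths 8→16→1,
  sigmoid output). The depth is fixed by design; the widths are this
  package's choice.
- The output projection is zero-initialised, so a freshly built block is
  exactly the identity through its residual connection — it can be
  inserted into a pretrained graph without perturbing it, and the
  property doubles as an exact unit test.

Windowing reduces the attention-score storage from `(HW)²` to
`Ws⁴ (H/Ws)(W/Ws)` entries per head; the suite asserts the exact score
tensor size at `H = W = 56`, `Ws = 7`.

## Space-preserving convolution

`aspc_forward` computes `F_out = M_ch ⊙ (M_sp ⊙ Conv₃ₓ₃(SPD(F_in)))`.
SPD moves each 2×2 spatial block into four channel groups, ordered
top-left, top-right, bottom-left, bottom-right (the ordering is a
convention this package fixes and documents; the transform itself is the
contract). Odd extents are zero-padded right/bottom so the transform
stays bijective on the padded grid. Spatial attention is applied before
channel attention — the composition formula is followed literally even
though the CBAM lineage it cites applies channel attention first.  Both
attention maps are computed from the convolution output. The 3×3
convolution maps `4C` directly to the configured output width; the
channel bottleneck reduction defaults to `r = 16` (standard bottleneck
practice).

## Dual-adaptive dynamic upsampling

Two branches predict offsets (`1×1`: pointwise, content-global; `3×3`:
neighbourhood-aware) of shape `B×2Gs²×H×W`, in units of source-grid
cells. They are fused convexly with weight `sigmoid(alpha_raw)`; the raw
scalar is stored unconstrained and initialised to 0.5, so the effective
initial weight is σ(0.5) ≈ 0.622 — the published "initialised to 0.5" is
read as the raw parameter, since the fusion formula applies the sigmoid
explicitly. Sampling positions are `P_base + Δ`, normalised to \[−1, 1\]
(the standard grid-sampling convention; a stray citation marker in the
source text's "(−15; 15)" was resolved in favour of \[−1, 1\]) with an
align-corners-false cell-center base grid, so zero offsets reduce the
block to plain bilinear-style resampling at any scale. Groups are
sampled independently and concatenated along channels, which preserves
the `B×C×sH×sW` output contract; `G = 4` by default (`G = 2` in the
reduced detector). In PL mode a pixel shuffle performs the coarse
upsample first and the offsets refine at scale 1. The optional dynamic
scope multiplies offsets by a σ-squashed factor from an auxiliary 1×1
conv, so magnitudes can only shrink.

## Colorimetry

Pixel rules in HSV (hexagonal conversion, hue in \[0, 360), saturation =
delta/max) with 8-bit RGB side conditions:

| class | hue | saturation | RGB |
|---|---|---|---|
| ripe | \[0, 20) ∪ \[340, 360) | > 0.6 | R > G + 15 and R > B + 15 |
| semi-ripe | \[20, 60) | — | \|R − G\| ≤ 20 or 0 < R − G ≤ 30 |
| unripe | \[60, 120) | \[0.35, 0.85\] | G > R and G > B |

Evaluation precedence is ripe → semi-ripe → unripe (ripe has the
strictest compound condition, so overlap at interval boundaries resolves
toward it); anything else is unclassified. Hue intervals are half-open
above except the wrap-around red interval. The "R ≈ G" tolerance (20)
and "slightly greater" margin (30) are package constants chosen for the
qualitative wording; saturation bounds are taken as inclusive, and
semi-ripe carries no saturation constraint because none is stated.
`classify_box` turns pixel labels into a box label by majority vote over
classified pixels.

# The synthetic generator

`render_scene` draws radially shaded fruit disks whose base colors are
sampled from the *interior* of the colorimetric threshold regions, with
enough margin that the 0.75–1.0 multiplicative shading cannot move a
pixel across a class boundary (hue and saturation are invariant under
multiplicative shading; the RGB margins shrink, so colors are sampled
with widened margins and verified at both shading extremes). Elliptical
leaf occluders in low-saturation greens (never classifiable as fruit)
are drawn above the fruits. Occluded fractions are measured exactly on
pixel masks — the fraction of each disk covered by anything drawn later —
matching a visible-area notion of occlusion rather than a box-IoU proxy.
Fully hidden fruits stay annotated with fraction 1.

The default `scene_spec()` *is* the emulated study regime: 640×640
scenes, 30 fruits of radius 6–14 px (boxes < 32×32), 45% of fruits in
tight clusters (`sd = 9` px around 6 cluster centers, bringing
nearest-neighbour distances below 15 px for roughly a third of fruits)
and a 0.30 per-fruit dedicated-occluder probability. The two placement
and occluder knobs were set so the generator reproduces the regime's
published summary statistics — about 40% of fruits more than 30%
occluded and about a third in sub-15 px clusters — as measured over
hundreds of seeded scenes; they are conditions of the test bed, not free
parameters of any test. What the generator does **not** emulate: real
foliage texture statistics, specular highlights, perspective and defocus,
correlated illumination fields, or annotation noise. Tests that pass on
these scenes therefore verify the mechanisms and their contracts, not
field accuracy.

`augment` applies the study's augmentation recipe (flips, ±15° rotation,
random crop, multi-scale resize; brightness ±30%, contrast ±25%, hue
±10°, saturation ±30%). Geometric transforms are composed as one affine
map applied to both image (nearest-neighbour inverse mapping, preserving
exact colors) and boxes (transformed-corner hulls, clipped, dropped below
4 px²); photometric jitter never touches boxes. `write_dataset` writes
PNG images, YOLO label text and 32-bit float TIFF condition rasters in a
70/15/15 split whose realised sizes are within one scene of the exact
fractions.

# The detector assembly

`assemble` builds a reduced-width one-stage graph: backbone stem plus
four downsample stages (ASPC when toggled, 3×3 conv + 2×2 average pool in
the baseline), a PAN neck whose two top-down upsamples are DADU blocks
(nearest-neighbour in the baseline), a bottom-up path, CGWA applied to
each of the three output scales (strides 4, 8, 16), and anchor-free 1×1
heads predicting center offset (sigmoid), log size in stride units,
objectness and class logits. All toggles off reproduces the plain
baseline graph, and each toggle adds parameters, so ablation structure is
testable even though ablation *accuracy* ordering is training-stochastic
and deliberately not asserted.

At inference the density condition cannot come from annotations; the
default source is an auxiliary two-conv head at stride 4 trained against
the offline ground-truth maps (an MSE term in the loss), with
`offline_gt` retained for unit tests and `uniform` as an ablation.
Training uses full-batch Adam on balanced BCE objectness, per-class BCE
and L1 box regression; each ground-truth box supervises the cell
containing its center at every scale. Score and IoU ties in NMS and in
evaluation matching break toward the lower box index, which makes runs
bit-reproducible; checkpoints are single RDS files embedding the config.

Evaluation follows the standard protocol: per class, detections sorted by
descending score greedily match unmatched truths at IoU ≥ 0.5; AP is the
all-point interpolated area under the precision envelope; mAP@0.5 is the
unweighted class mean; precision/recall/F1 are reported at a 0.25
operating point; the confusion matrix holds ground truth in rows,
predictions in columns, with a background row for false alarms and a
background column for misses. The CAM utility is a minimal
gradient-weighted activation map (channel weights = mean gradients of the
summed objectness), min–max normalised with an all-zero guard.

# Problem sizes and numerical choices

The test and acceptance workloads are scaled to a single CPU core as the
package's own study sizes: training fixtures use 64×64 scenes with 3
fruits and a `base_channels = 8` model (about 0.55 M parameters), trained
for 200 full-batch steps at learning rate 5e-3 — enough for the full
assembly to overfit eight easy scenes to mAP@0.5 = 1.0. Statistical
generator checks use 200 scenes at the full 640×640 default regime.
Numerical guards: density normalisation adds 1e-6 to the maximum;
occlusion maps guard `s_global < 1e-6`; softmax subtracts row maxima;
padded attention keys get −1e9 logits; bilinear sampling clamps to the
border and zeroes positional gradients once a coordinate is fully
clamped; degenerate (zero-area) boxes and out-of-range box centers raise
validation errors naming the offending box.

# Known limitations

- The autodiff tape favours clarity over throughput; wall-clock budgets,
  not correctness, set the problem sizes above.
- The occlusion map is a heuristic visibility proxy; it is not learned
  from data and does not separate occluder types.
- Published absolute accuracy and complexity figures for the full-scale
  field model (e.g. headline mAP on orchard photographs, 30 M-parameter
  variants) require the original dataset and GPU-scale training and are
  out of scope; the reduced assembly demonstrates the mechanisms and
  their learning behaviour, not field performance.
- `cam_heatmap` assumes square inputs; nearest-neighbour augmentation
  resampling trades interpolation quality for exact color preservation.
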