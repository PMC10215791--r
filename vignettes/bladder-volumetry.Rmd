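---
title: "Automatic bladder volumetry from biplane ultrasound: model, training and measurement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic bladder volumetry from biplane ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Post-void residual (PVR) urine volume is a routine quantity in urology.
B-mode ultrasound is the standard non-invasive way to obtain it, but reading
bladder images requires expertise that point-of-care settings often lack.
`echovol` implements a fully automatic pipeline for low-resource devices: a
compact multitask convolutional network detects and segments the bladder on
a sagittal + transverse image pair, a geometric post-processor turns the two
masks into depth, height and width, and a shape coefficient converts the
axis product into a volume:

$$ V \approx c \cdot D \cdot H \cdot W $$

with $D$ measured on the sagittal plane, $H$ and $W$ on the transverse
plane (in cm), and $c$ a shape coefficient (0.52 for a sphere, 0.66
triangular prism, 0.72 "unknown", 0.81 cylinder, 0.89 cuboid). Because the
deployment target is an embedded system-on-chip, the network is designed to
quantize cleanly to 8-bit fixed point, and the package implements that
quantization path end to end.

Everything is testable without any external data: the package ships a
synthetic biplane phantom simulator with exact ellipsoidal ground truth.

## The network

The model (built by `build_model(model_config())`) is a single shared
encoder with two heads:

* **Backbone.** Inverted-residual bottleneck stages (expand 1x1 ->
  depthwise 3x3 -> project 1x1, each with batch normalization and ReLU6),
  single-channel input, truncated immediately after the stride-16 stage
  whose output has 96 channels. A 192 x 192 input yields a 12 x 12 x 96
  feature map.
* **Segmentation path.** Two parallel branches: a chain of two *quantizable
  squeeze-and-excitation* (QSE) blocks (96 -> 96 -> 256 channels) and a
  stack of two 3 x 3 convolutions (96 -> 64 -> 256). The branches
  concatenate to 12 x 12 x 512, a depthwise-separable block merges them
  back to 256 channels, a 1 x 1 convolution reduces to the two classes, a
  single x16 bilinear upscale restores 192 x 192, and a per-pixel softmax
  finishes the head.
* **Classification path.** Global average pooling of the backbone features
  (1 x 1 x 96), one dense layer to 2 logits, softmax.

The QSE block injects global channel context without the elementwise
activation-by-activation multiplication that makes the classical SE block
awkward to quantize: the global-average squeeze vector is *tiled* back to
the spatial grid, *concatenated* with the input, and mixed by a 1 x 1
convolution. `check_quantization_friendly()` walks the layer-descriptor
graph and certifies that no multiply node exists.

The default configuration counts 951,556 trainable parameters
(`count_parameters()`), inside the sub-million budget the design targets;
the budget is enforced at construction time. Channel choices that are not
fixed by the head endpoint dimensions (the first 3 x 3 conv at 64
channels, the first QSE block at 96) were picked so the exact layer-wise
count lands inside that budget; two stacked 256-channel 3 x 3 convolutions
alone would cost 0.81 M parameters and break it.

All tensor compute (im2col GEMM convolution, depthwise convolution,
batch-norm statistics, bilinear resampling, and their adjoints) is
implemented in compiled code under `src/`; the backward passes are verified
against finite differences in the test suite.

## Training procedure

Training is staged so neither task degrades the other
(`train_stage()` / `train_pipeline()`):

1. **Stage 1 — segmentation.** Backbone + segmentation path train on
   bladder-positive images only (masks exist only for those), with the
   classification head frozen. The loss is the combo loss
   $\alpha \cdot \mathrm{CE} + (1-\alpha)(1 - \mathrm{softDice})$ with
   $\alpha = 0.5$ by default (the balanced setting of the combo-loss
   family); soft Dice is computed without a smoothing term whenever the
   denominator is positive.
2. **Stage 2 — classification.** Backbone and decoder are frozen and run in
   inference mode (so even their normalization statistics are untouched —
   the test suite checks bit-identity of the frozen weights); only the
   dense head trains, under cross-entropy, on positives + negatives.
   Because the backbone is frozen its pooled features are computed once and
   cached, which makes this stage cheap.
3. **Stage 3 — merge.** `merge_paths()` takes backbone + decoder from stage
   1 and the dense head from stage 2. The paths are disjoint, so the merged
   model's outputs are bit-identical to the respective stage models'.

Optimization is Adam (initial rate 1e-3), with reduce-on-plateau scheduling
(factor 0.5 after 5 stagnant validation epochs) and early stopping
(patience 20 epochs, best validation weights restored). Augmentation is a
random uniform intensity shift (+-25 grey levels) and a random left-right
flip of image and mask together. Every stochastic element is derived from
`train_config()$seed`, and two runs with the same configuration produce
identical histories.

### Quantization

Quantization-aware training fake-quantizes every weight tensor onto the
per-tensor symmetric int8 grid in the forward pass (straight-through
gradients; `fake_quantize()` is an idempotent projection). After training,
`quantize_model()`:

1. folds batch normalization into the preceding convolutions,
2. stores per-tensor symmetric int8 codes and scales for all weights,
3. calibrates per-node affine uint8 activation ranges on a calibration set,
4. simulates integer inference by de-quantized arithmetic with activation
   fake-quantization at every node boundary.

Weight quantization is per-tensor symmetric (not per-channel) to mirror a
flat fixed-point deployment; activations are per-tensor affine. An all-zero
calibration activation degenerates to scale 1 with a classed warning.
Biases are kept in float, as is conventional when they are consumed at
accumulator precision. On the synthetic validation split the quantized
model's mean Dice is within measurement noise of the float model's (the
acceptance run reports the exact drop).

## Axis detection and volume estimation

Given the two native-grid masks (`postprocess_segmentation()` resizes the
192-grid argmax back by nearest neighbour):

* `largest_region()` keeps the largest 8-connected component.
* **Depth (sagittal).** `min_area_bbox()` finds the minimum-area rotated
  rectangle of the region by rotating calipers over the convex hull of the
  foreground pixel centres (cross-checked in the tests against a dense
  brute-force angle scan and against an independent computational-geometry
  implementation). Along each of the two box diagonals the chord between
  the first and last intersection with the region is measured
  (outermost pair, so non-convex regions are handled); the greater chord,
  scaled by the pixel spacing, is the depth. On an exact tie either
  diagonal is valid; the diagonal from the top-left corner is taken. An
  axis-aligned box mode (`rotated = FALSE`) exists for comparison: note
  that on a rasterized ellipse the true minimum-area box is very slightly
  tilted (pixel jaggies), so the two modes can differ by a few percent.
* **Height / width (transverse).** Global maxima of the per-column vertical
  and per-row horizontal first-to-last foreground extents, times spacing.
* `estimate_volume()` applies $V = c \cdot D H W$ with the axes converted
  to cm. The default label is `"unknown"` ($c = 0.72$, the value the
  measurement table validates; the 0.7 sometimes cited from the older
  literature is not used).

`auto_measure()` gates everything on the classification head: if either
plane is classified bladder-free, the segmentation is considered invalid
and no volume is emitted. All geometry is computed in pixels and converted
to physical units only at the end; the pixel spacing always travels as
metadata.

## The phantom simulator

No public dataset exists for this problem, so `phantom_sim` emulates one.
A phantom is an ellipsoid with exact semi-axes, pose and centre
(`sample_phantom()` inverts $V = \tfrac43 \pi abc$ exactly). Rendering
(`render_biplane()`):

* The sagittal and transverse planes cut the ellipsoid through (near) its
  centre; free-hand probe placement is emulated by a per-plane off-axis
  offset of up to 20 % of the out-of-plane semi-axis (`plane_jitter`,
  set to 0 for oracle tests and volume measurements).
* Texture is fully developed multiplicative speckle: exponential intensity
  (the squared magnitude of complex circular Gaussian scattering) times an
  echogenicity map, log-compressed to uint8. The bladder interior is
  anechoic (3 % of background echogenicity), with optional posterior
  enhancement below it and random soft-tissue inhomogeneities elsewhere.
  `speckle_scale = 0` gives the noise-free limit in which the mask boundary
  is the exact level set.
* Masks are the exact rasterized analytic cross-sections; the imaging
  sector (default 110 degrees, apex at the top-middle) is cosmetic and
  never touches the masks. The sector is wider than a phased cardiac
  sector because the largest phantom the protocol uses (300 mL, 41.5 mm
  radius) must fit the 115.5 mm-deep grid; 110 degrees is typical of
  curved abdominal arrays.
* A 570 x 330 grid at 0.35 mm/px is the default; spacing is metadata
  everywhere, never hard-coded.

What the simulator does **not** model: beamforming and diffraction physics,
attenuation, refraction and shadowing artifacts, anisotropic resolution,
probe pressure deformation, and anatomical context (pelvic bone, prostate,
uterus). Passing tests on this simulator therefore demonstrates that the
architecture can learn and that the geometry, training, and quantization
machinery is correct — not that the shipped weights transfer to clinical
images; on real data the network must be retrained.

`make_dataset()` writes PNG images and masks plus a CSV manifest; the whole
dataset is a pure function of one master seed, with per-sample seeds,
volumes, poses and feasible centre positions derived from it.

## Reference study and problem sizes

`run_reference_study()` is the package's end-to-end protocol, also invoked
by `scripts/acceptance.R`: 128 + 128 training pairs (256 positive and 256
negative images), 32 + 32 validation pairs, segmentation stage capped at 8
epochs (the validation Dice plateaus around 0.97 by then on this task;
the last epochs mostly mature the features the detection head pools),
classification stage at 60 (cheap, since the frozen backbone's pooled
features are cached), int8 quantization calibrated on 32 mixed
training images, and automatic measurement of 30 spherical phantoms (10
each at 50 / 150 / 300 mL, c = 0.52, 5 independent renders each in
`evaluate_run()`'s protocol, one in the study), both with the trained
quantized model and with ground-truth masks injected. The oracle-mask run
isolates the geometric estimator (median absolute error well under 1 %,
bounded analytically by the -0.69 % sphere bias of c = 0.52 plus
rasterization); the trained run adds segmentation error on top.

## Numerical choices and edge cases

* ReLU6 everywhere (quantization-standard); batch-norm epsilon 1e-3,
  running-statistics momentum 0.9.
* Weight init: He-normal for convolutions, scaled-normal for the dense
  layer; all seeded.
* Dice between two empty masks is defined as 1 (never triggered on bladder
  images, stated for completeness); volume errors are signed internally and
  summarized as magnitudes.
* Empty masks raise classed no-region errors; a diagonal meeting the region
  in fewer than 2 pixels raises a degenerate-region error; out-of-view
  phantoms name the offending semi-axis.
* Single x16 bilinear upscale by default (`upsample_steps = 2` gives two
  x4 steps); stride-2 convolutions use symmetric padding.
* Left-right flip equivariance holds exactly only for stride-1 graphs
  (stride-2 sampling lattices break it), so the equivariance check runs on
  a constructed stride-1 model with symmetrized kernels.

## Known limitations

* The simulator's speckle is spatially white; real speckle has a
  point-spread-function-induced correlation length.
* Shape coefficients assume the operator picked the right bladder shape
  class; the study design cannot validate coefficient choice on synthetic
  ellipsoids beyond the spherical case.
* Per-tensor weight quantization is slightly lossier than per-channel; it
  was chosen to mirror flat fixed-point deployment.
* Throughput/latency on embedded hardware is out of scope here; parameter
  count is the only complexity metric the package reports.
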