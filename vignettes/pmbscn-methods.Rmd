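---
title: "PMB-SCN: model, training recipe and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PMB-SCN: model, training recipe and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The recognition problem

Daily behavior statistics — how much a pig feeds, lies, moves, scratches
or mounts — are an early indicator of health and welfare, and grooming
(scratching) in particular cannot be recognized from an animal's position
alone: the animal does not move from its spot, only a body region
oscillates. PMB-SCN therefore classifies *video clips* rather than
detections in single images. The input is a short clip of a single animal;
the output is one of five behaviors: feeding, lying, motoring, scratching,
mounting — in this fixed vocabulary order everywhere in the package.

## The dual-pathway network

PMB-SCN follows the SlowFast two-pathway idea with a two-layer
basic-block 3D-ResNet backbone:

* a 64-frame window is drawn from the raw clip;
* the **slow pathway** samples every 8th frame (8 frames) and carries wide
  channels (64 at the stem, then 128, 256, 512, 1024 through res2–res5 in
  the full 34-layer variant);
* the **fast pathway** samples every 2nd frame (32 frames) and carries
  `beta = 1/8` of the slow widths at every stage;
* neither pathway ever downsamples time; spatial downsampling (stride
  1×2×2) sits on the first convolution of the entry block of res3–res5,
  giving spatial sizes 112, 56, 56, 28, 14, 7 from a 224×224 crop;
* temporal (3×3×3) kernels appear only in res4/res5 on the slow pathway
  but in every residual stage of the fast pathway; the second layer of
  every block is a spatial-only 1×3×3 convolution;
* after res2, res3 and res4 a **lateral connection** carries fast features
  into the slow pathway: a 5×1×1 convolution with temporal stride 4 and
  2× the fast channel width aligns the temporal lengths (32 → 8);
* after res5, both pathways are globally average-pooled, concatenated
  (1024 + 128 features in the full variant), passed through dropout 0.5
  and a softmax classifier.

Three published variants are available through `make_arch_spec()`:
`pmb-scn-34` (block counts 3,4,6,3), `pmb-scn-34half` (all residual
widths halved) and `pmb-scn-18` (block counts 2,2,2,2).

### Lateral fusion: why concatenation is the default

The textual description of the lateral connection calls for *addition*
fusion, but a transform with "2× the fast channel width" cannot be added
to the slow tensor: 2 × 16 ≠ 128 channels at res2. Two dimensionally valid
readings exist:

* **concat** (the original SlowFast choice): the transformed fast features
  are concatenated onto the slow channels, widening the next stage's entry
  block;
* **project_sum**: a 1×1×1 projection maps the transform to the slow width,
  then adds elementwise.

The published parameter table settles the question. Counting every
trainable scalar of the three variants under concatenation fusion gives
165.44 M, 41.40 M and 86.00 M — each within 0.05 % of the printed 165.46,
41.41 and 86.03 M (and the printed "quartering" ratio, 0.2502, falls out
exactly). Under project_sum the counts land ≈ 3 % low. Concatenation is
therefore the default (`fusion = "concat"`); `project_sum` remains
available behind the flag. The residual convolutions carry no bias
(normalization supplies the shift), projection shortcuts (1×1×1 conv +
norm) appear whenever a block changes channel count or stride, and
normalization scale/shift parameters are included in all counts.

## Training recipe

`train()` implements the published optimization settings exactly:

| parameter | value | note |
|---|---|---|
| optimizer | SGD, momentum 0.9 | single-device batch statistics |
| batch size | 8 | |
| base learning rate η | 0.0125 | |
| schedule | η·0.5·(cos(π·n/n_max)+1) | n = mini-batch iteration |
| warm-up | linear, 0.1·η → cosine | default 34 epochs' worth |
| weight decay | 1e-4 | weights only, not norm/bias |
| dropout | 0.5 | on the concatenated pooled feature |
| loss | cross-entropy on softmax | |

Weights start from a zero-mean Gaussian with variance `2/n_l` per layer
(`n_l` = receptive-field volume × input channels, the fan-in), biases and
normalization shifts at zero, normalization scales at one
(`init_weights()`). Two conventions are not stated by the source
description and are package choices: the warm-up span (34 epochs' worth of
iterations, starting at 0.1·η — configurable; short runs scale it down
proportionally, e.g. 3 epochs for a 30-epoch run) and the reading of
"iteration" as a mini-batch step, so `n_max` = steps/epoch × epochs.
Pixels are scaled to [0, 1] and standardized with fixed constants
(mean 0.45, sd 0.225) on all channels. Training crops are random 224×224
patches taken after scaling the shorter side to 240 — the crop size is
prescribed; applying the same shorter-side convention as inference keeps
the train/test scale consistent. No flips or color jitter are applied.

## Inference protocol

Each test clip becomes exactly 30 views: 10 temporal windows uniformly
spaced along the clip × 3 square crops of 240 px placed at the first,
center and last offsets along the longer axis after scaling the shorter
side to 240. Clips shorter than 64 frames are loop-padded (wrapped), which
preserves the motion statistics of periodic behaviors — zero padding would
not. The 30 per-view softmax vectors are averaged and the argmax taken,
ties broken toward the lowest class index for determinism. *Top-1
accuracy* counts per-sample decisions; *views accuracy* counts each of the
30×N individual view argmaxes. The per-class rate reported from confusion
matrices is the row-wise (ground-truth-conditioned) diagonal — i.e.
per-class recall; rows with no samples give `NA`.

## The synthetic behavior generator

The source footage is not publicly deposited, so the package ships a
generator (`generate_clip()`, `generate_dataset()`) whose five classes are
separable by exactly the spatiotemporal signatures that distinguish the
real behaviors:

| class | signature | default parameters |
|---|---|---|
| lying | static body | — |
| feeding | head region oscillating vertically | 0.06 cycles/frame, 5 px |
| motoring | whole-body translation (bouncing) | 1 px/frame |
| scratching | region oscillating against a fixture edge | 0.30 cycles/frame, 7 px |
| mounting | second body rising onto the first | two objects |

Scratching's frequency is strictly above feeding's, encoding the premise
that the two behaviors share a movement rule but differ in speed; mounting
is the only two-object class, as it is defined by contact between two
animals. Objects are soft-edged ellipses on a fixed hatch background;
intensity, position jitter and color tint are drawn per clip from a seeded
RNG so absolute brightness carries no class signal; noise is additive
Gaussian (default sd 4 of 255, a realistic sensor floor), clipped to the
8-bit range. The default scene is 64×64 px so CPU experiments stay fast;
full 320×240 scenes are available by configuration.

A deliberately network-independent check accompanies the generator: a
nearest-centroid rule over two hand-crafted features — frame-difference
energy above the clip's own noise floor, and the dominant temporal
frequency of the most motion-active pixels — separates the five default
classes at ≥ 95 % on 20 clips/class. The noise floor is the median
per-pixel difference energy (motion is localized, so the median pixel sees
only noise); energy is compared on a log scale and frequency on a log
(octave-like) scale, their natural scales.

What the generator does **not** emulate: photorealism, occlusion, pen
clutter, multiple freely moving animals, illumination changes and camera
noise structure. Tests passing on synthetic data therefore demonstrate
that the architecture, sampler, optimizer and evaluator are implemented
correctly and that the network can learn spatiotemporal class signatures —
they say nothing about accuracy on real pig footage.

## Desk-scale experiment sizes

The published headline accuracies (97.63 % / 96.35 % top-1/views on the
in-domain test set; 91.87 % / 84.47 % on the cross-pigsty set) were
obtained by training the 165 M-parameter network for 300–400 epochs on
GPU hardware with footage that is not public; they are not reproducible
here. The package covers them two ways:

* the two printed cross-pigsty confusion matrices are recomputed by
  `metrics_from_confusion()`, reproducing 91.87 % and 82.93 % top-1 and the
  per-class rates to two decimals;
* a learnability experiment trains a reduced configuration — channels ÷ 8,
  residual block counts (1,1,1,1), 16-frame windows (slow 2 / fast 8
  frames), 64 px crops — for 30 epochs on 50 synthetic clips per class
  (32-frame, 64×64 scenes) and evaluates the full 30-view protocol on a
  held-out synthetic set of 20 clips per class. Under seed 1 this reaches
  100 % held-out top-1 (the acceptance threshold is ≥ 90 %), in roughly
  ten minutes on one CPU core.

All randomness (generator, initialization, shuffling, windows, crops,
dropout) flows from explicit integer seeds, so every experiment in the
test suite is exactly reproducible.

## Numerical choices and degenerate inputs

* Convolution padding is "same"-style everywhere, so kernels never change
  extents beyond their stride; the fast stem's 5-frame kernel gets
  temporal padding 2, the lateral 5×1×1 transform likewise.
* Batch-norm uses eps 1e-5 and momentum 0.1 for running statistics;
  evaluation mode uses the running statistics, making single-sample and
  batched inference identical.
* Softmax and cross-entropy are computed with max-shift stabilization; a
  non-finite loss aborts training with a diagnostic rather than continuing.
* Argmax ties break toward the lowest class index (vocabulary order).
* Clips shorter than a window wrap; windows never index outside the clip.
* `stage_output_shapes()` rejects inputs below 32 px, where the stride
  pyramid degenerates.
* Frame directories carry no frame rate; readers supply one (default 25).
* AVI support is a minimal uncompressed 24-bit RIFF/DIB implementation —
  lossless by construction, so write-then-read is bitwise identity; it
  does not read third-party compressed AVI streams.

## Known limitations

* Single-animal clips only; no tracking or multi-animal reasoning.
* No optical-flow or audio inputs; no Kinetics-style pretraining; the
  comparison backbones (C3D, MC4, rMC4, R(2+1)D, plain R3D, SlowFast-50)
  are out of scope.
* Training the full-width variants is computationally out of reach on a
  single CPU; they are exercised structurally (construction, counting,
  shapes, forward determinism) rather than trained.
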