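---
title: "Multiband subband decomposition and frozen-backbone fusion for fracture classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiband subband decomposition and frozen-backbone fusion for fracture classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavefrac)
```

## The model

A fracture is a localised discontinuity: in the frequency domain it is
broadband, while intact bone shading is low-pass. `wavefrac` therefore
classifies the *multiband decomposition* of a radiograph rather than its
raw pixels. The pipeline is:

1. **Decomposition.** A one-level separable 2D DWT under periodization
   splits each 128 x 128 channel into four 64 x 64 coefficient arrays
   (LL, LH, HL, HH). Inverting each band with the other three zeroed gives
   four *full-size* subband image tensors that sum exactly to the input.
   Working with full-size reconstructions (rather than the half-size
   coefficient arrays) lets every branch share one backbone input
   geometry, and makes the decomposition a pure, invertible re-encoding of
   the image.
2. **Branches.** Each subband tensor is min-max rescaled and passed
   through a frozen convolutional backbone; the flattened features feed
   two dense - batch-norm - dropout blocks and a sigmoid, yielding a
   per-band score.
3. **Fusion.** The scores, concatenated in the fixed order
   (LL, LH, HL, HH) restricted to the configured subset, pass through a
   dense(128, ReLU) layer and a final sigmoid.

Training minimises binary cross-entropy end-to-end over the head and
fusion parameters only. There is a genuine architectural ambiguity here:
the per-band sigmoids *could* have been pre-trained separately against
the class labels and only then fused. We train jointly with a single
loss at the fused output because one loss is what the cost function
defines, and joint training lets the fusion layer decide how much each
band matters. The same reasoning fixes the Grad-CAM target: saliency is
computed from the *fused* pre-sigmoid logit, not each branch's own score,
because the fused logit is the decision being explained.

## Tunable parameters

| parameter | default | why |
|---|---|---|
| input size | 128 x 128 x 3 | backbone geometry; even dyadic size for the DWT |
| wavelet family | `haar` | best-performing basis; db4/db5/db8 available |
| boundary mode | periodization | exact M/2 x N/2 coefficients and exact perfect reconstruction on even sizes; symmetric extension would oversize the Daubechies coefficient arrays |
| SVD grouping | 1-5 / 6-15 / 16-40 / 41-128 | coarse-to-fine eigentriple bands; last interval truncates to `min(M, N)` |
| branch head | dense 256, 128; dropout 0.3, 0.3 | standard taper between the flattened features and a scalar score |
| learning rate / batch / epochs | 0.001 / 32 / 50 | reference training recipe |
| early stopping | patience 5 on validation accuracy, best weights restored | reference recipe |
| split | 72 / 8 / 20 stratified | reference protocol; `floor` train, `round` test, remainder validation — the unique simple rounding that reproduces the reference per-class table |
| decision threshold | 0.5, ties positive | unstated upstream; the symmetric convention |
| k (cross-validation) | 5 | the reported protocol (10 is configurable) |

## Backbones: runnable vs descriptor

The environment this package targets has no deep-learning runtime and no
network access, so the published ImageNet backbones cannot be executed.
They are registered as **architecture descriptors** — per-stage
kernel/stride/padding and final channel width — from which the feature-map
shape contract is computed by stride arithmetic
(`backbone_feature_shape("efficientnetv2b2", c(128, 128, 3))` is
`4 x 4 x 1408`). The **tiny** backbone is the runnable one: three
conv(3x3) + ReLU + maxpool(2) blocks of 16/32/64 channels and a final
2 x 2 average pool (feature map 8 x 8 x 64), He-initialised from the run
seed and then frozen. A frozen random conv net is a legitimate member of
the frozen-extractor family (random convolutional features are a standard
kernel approximation); what it lacks is ImageNet semantics, so its
absolute accuracy is a desk-scale stand-in, not a reproduction.

Two numerical choices matter for the heads:

* **Feature standardisation.** Flattened backbone features are z-scored
  per dimension with training-set statistics (stored in the model, applied
  at inference, and chained through by Grad-CAM's backward pass). Raw
  activations have heterogeneous scales that slow Adam and leave the
  batch-norm running moments far from their initialisation.
* **Batch-norm momentum 0.9** (not the common 0.99). With a few hundred
  training images there are only ~10 batches per epoch; running inference
  moments must converge within the early-stopping window or validation
  accuracy is evaluated with stale statistics.

Batch normalisation uses batch moments in training and running moments at
inference (eps 1e-3); dropout is inverted (inference is a no-op); Adam
uses beta 0.9/0.999, eps 1e-7. One integer seed drives weight
initialisation, shuffling and dropout, so a fixed configuration
reproduces its history bit-for-bit on one machine.

## The synthetic world

The generator emulates only the statistical structure the method
exploits. A "bone" is an anti-aliased capsule (soft 6 px boundary,
quadratic transverse profile, mild longitudinal gradient, optional bow)
on a dark background with Gaussian pixel noise (sd 0.02); smooth regions
are locally near-linear, so a clean image has essentially no Haar HH
energy (the mixed second difference of a linear field is zero). The
fracture class adds a dark, jagged, piecewise-linear transverse crack
(width 2-4 px, contrast 0.6) — a localised broadband discontinuity.

What it does **not** emulate: radiographic physics (scatter, beam
hardening), anatomy (joints, trabecular texture, soft tissue), annotation
noise, or the multi-region fractures of real collections. A green
end-to-end test therefore establishes that the pipeline is wired
correctly and that the architecture can exploit subband-localised detail
— not that the reference accuracy on real radiographs is reproduced.
Class-count defaults (200/200 at training scale; the CLI accepts any
counts, including the imbalanced 717/3337 shape of public collections)
keep the desk-scale run inside a laptop-minutes budget.

## Degenerate inputs and conventions

* Odd image sizes are rejected (one-level dyadic analysis needs even
  sizes); unknown wavelet families and unregistered backbones fail fast.
* Min-max rescaling of a zero-range array maps to all zeros — used for
  display of signed detail bands and for all-zero-gradient saliency maps.
* Metrics with zero denominators (e.g. no positive predictions) are
  reported as 0 with a warning flag rather than an error, so a degenerate
  fold cannot abort a cross-validation run.
* AUROC uses the trapezoidal rule over distinct thresholds (equal to the
  Mann-Whitney correct-ranking probability with ties counted half);
  AUPRC uses step interpolation.
* Fold summaries report the population standard deviation (divisor k),
  the convention under which the reference fold table's spread
  reproduces.
* A checkerboard worth noting: the 0/1 checkerboard has *equal* Haar HH
  and LL subband-image energy (the mean sits in LL), so the package's
  tests assert HH dominance only over the LH/HL bands for that input.

## Known limitations

* The ImageNet backbones are shape contracts only; plugging in real
  pretrained weights would require a deep-learning runtime and is out of
  scope.
* Single-level decomposition only, and only the four named wavelet
  families.
* Training is plain R + BLAS; fine at the desk scale this package
  targets (hundreds of images), not at collection scale (thousands).
* The synthetic discriminative margin in HH energy is intentionally
  modest (noise contributes comparable HH power); the classifier relies
  on spatial structure across all bands, which is exactly the design
  premise.
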