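---
title: "Detecting fungiform papillae by heatmap regression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fungiform papillae by heatmap regression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fungiform)
```

## The problem

Fungiform papillae (FPs) are the mushroom-shaped structures on the anterior
tongue that carry most taste buds; their density varies widely between
people and correlates with taste sensitivity. The standard way to count them
is to stain the tongue with blue food dye — FPs stain lighter than the
surrounding filiform papillae — photograph a small circular region, and have
trained observers click every papilla. That is slow, subjective, and does
not scale.

`fungiform` implements an automatic counting pipeline: photographs are
normalized, a convolutional encoder–decoder network regresses a continuous
*heatmap* whose peaks sit at papilla centers, and peak extraction plus
point matching turn that map into counts and error rates. Because clinical
photographs of this kind are not freely distributable, the package also
ships a synthetic scene generator with exact ground truth, which is what
the test suite and the bundled experiment run on.

## Pipeline

1. **Stain-region detection.** The image is projected onto a stain-color
   axis (default `blue − red`), thresholded by Otsu's method, cleaned by
   morphological closing, and the largest connected component is fitted
   with an ellipse from its second-order moments (for a filled ellipse the
   semi-axes are twice the standard deviations along the principal
   directions).
2. **Crop and resize.** A square of side $2(1+m)\max(a,b)$ (margin
   $m = 0.05$) centered on the ellipse is cropped, shifted — never shrunk —
   at image borders, then resized bilinearly to the working resolution of
   $250 \times 250$ px. Point annotations are mapped analytically through
   the same transforms (never resampled), with points outside the crop
   dropped and counted.
3. **CLAHE.** Contrast-limited adaptive histogram equalization (clip limit
   2, $8\times8$ tiles) is applied to the luminance channel by default,
   with the color channels rescaled proportionally; a per-channel mode is
   available. Whether equalization should act on luminance or per channel
   is genuinely open; luminance preserves hue and is the default.

Coordinates are `(row, col)`, 0-based, pixel centers at integer positions,
everywhere in the package.

## Ground truth and peak decoding

Each annotated center contributes a unit-peak isotropic Gaussian
$\exp(-d^2 / 2\sigma^2)$. Overlapping kernels are combined with a pixelwise
**maximum**, not a sum: targets then stay in $[0,1]$, which keeps the
linear-output regression bounded and reads as "one bright spot per
papilla" rather than an additive density. The kernel width defaults to
$\sigma = 3$ px at $250\times250$, matching the apparent papilla radius at
that resolution; it must stay well below half the minimum papilla
separation or peaks merge.

Decoding inverts the encoding: a pixel is a peak candidate if it is maximal
in its $(2d+1)$-square neighborhood ($d = 3$ px), reaches a relative
threshold (0.2 of the map maximum) and an absolute floor (0.05, which
silences near-empty prediction maps whose maximum is noise). Candidates are
accepted greedily by decreasing value with deterministic ties (smaller row,
then column), suppressing anything within $d$ Chebyshev pixels, so plateaus
yield exactly one peak. Peaks are reported at integer positions; sub-pixel
refinement is deliberately omitted because the evaluation's matching radius
absorbs quantization. For any point set with pairwise separation above
$2d$ and margins of $3\sigma$, decoding recovers the encoded points
exactly — the test suite asserts this on hundreds of random sets, and
checks the detector against a brute-force local-maximum scan.

## The three networks

All three architectures are image-to-image regressors ending in a **linear**
single-channel $1\times1$ convolution — the output is a continuous map, not
a class probability.

* **Classic U-Net**: four encoder blocks of two same-padded $3\times3$
  convolutions (64, 128, 256, 512 filters), a 1024-filter middle block,
  $2\times2$ max-pool downsampling, and a mirrored decoder using $2\times2$
  transposed convolutions with skip concatenation. No normalization or
  dropout. ~31M parameters at full width.
* **Optimized U-Net**: a leaner variant — 64, 64, 128, 256 encoder filters
  and a 512-filter middle block — with batch normalization after every
  convolution and dropout after each block (0.2; 0.5 in the middle block).
  ~7.9M parameters, a quarter of the classic network.
* **MultiResUNet**: MultiRes blocks (three chained $3\times3$ convolutions
  whose outputs are concatenated, plus a $1\times1$ residual projection)
  with the standard filter budget $W = \alpha \cdot 32 \cdot 2^{s}$,
  $\alpha = 1.67$, split $W/6$, $W/3$, $W/2$; skip connections are
  residual paths whose length shrinks with depth (4, 3, 2, 1 units).

Choices the architecture descriptions leave open, fixed here: hidden
activations are ReLU (the U-Net convention); kernels are $3\times3$;
downsampling is max-pooling and upsampling transposed convolution; network
input is the 3-channel CLAHE image (grayscale supported). Because 250 is
not divisible by $2^4$, inputs are reflection-padded to the next multiple
of 16 and outputs cropped back, preserving the stated interface.

### The engine

No deep-learning framework is used: convolution, transposed convolution
and pooling are implemented as im2col/GEMM kernels in C++ (RcppArmadillo),
with batch normalization, dropout, ReLU, Adam and the computation graph in
R. Backpropagation is written by hand and verified against central finite
differences in the test suite (mixed tolerance `1e-6 + 1e-3·|g|`, which
absorbs cancellation noise on near-zero gradients such as convolution
biases that a following batch-norm exactly cancels).

Initialization is He-normal, except the final linear head which is drawn
near zero (sd $10^{-2}$): predictions then start at the empty map and grow
peaks, the usual choice for heatmap-regression output layers. This matters
quantitatively here because Adam moves each weight by at most
`learning_rate` per step, so at `1e-3` a few hundred steps cannot undo a
badly scaled output layer.

## Training protocol

Five-fold cross-validation: ids are shuffled once under the master seed and
split into folds differing in size by at most one; every sample validates
exactly once. Per fold the published protocol is 500 epochs, batch size 2,
pixelwise MSE loss, MAE monitored per epoch, Adam at learning rate
$10^{-3}$, no early stopping (final-epoch weights are returned; best-epoch
selection is left to evaluation). Augmentation applies, with probability
0.8 per sample: horizontal/vertical flips, quarter turns, a free rotation
in $\pm15°$ (reflection padding for the image, zero padding for the
heatmap, both re-clamped), and an image-only intensity adjustment
(multiplicative $[0.9, 1.1]$, additive $\pm 0.05$). Geometric operations
are applied identically to image and heatmap so peaks stay aligned — a
property the tests check through the actual augmentation path. One master
seed derives the fold split, weight initialization and the
augmentation/dropout stream, so runs are exactly reproducible.

### Desk-scale preset

Full-protocol training is a GPU-days workload. For laptop-class
experiments and the package's own test suite, `desk_preset()` fixes a
deliberately scaled-down surrogate: $128\times128$ synthetic scenes, the
optimized U-Net at 1/8 filter width (~125k parameters), 50 epochs, batch 2,
learning rate $10^{-3}$. These sizes are the package's own choice of a
problem that a single CPU solves in minutes while still exercising every
pipeline stage; results under the preset characterize the pipeline, not
full-scale accuracy. It is always labelled a surrogate and never silently
substituted.

## Evaluation

Per image, against the Gaussian ground truth: **MAE** (mean absolute pixel
error), **SSIM** (Gaussian window, width 11, $\sigma=1.5$, standard
constants $C_1 = 0.01^2$, $C_2 = 0.03^2$, symmetric padding, averaged over
all pixels), and **Dice** after binarizing both maps at 0.5 of the unit
peak amplitude (both-empty masks count as 1; a soft variant was considered
and rejected to stay close to the "pixels that coincide" reading).

Detection quality uses the field's terminology: matched predictions are
**TPs**, spurious predictions **UPs** ("untrue positives"), missed papillae
**UNs**. Matching is an optimal one-to-one assignment — maximize matched
pairs within the radius, then minimize total distance — solved by an
$O(n^3)$ shortest-augmenting-path routine and verified against exhaustive
enumeration in the tests; greedy nearest-first matching is order-dependent
and can lose matches, so it is not used. The matching radius is nowhere
standard; the default is 5 px at $250\times250$ (papilla radius plus peak
quantization) and is reported in every evaluation header, because TP/UP/UN
numbers are meaningless without it.

Rates follow the conventional definitions: TP rate $= TP/GT$, UN rate
$= UN/GT$, UP rate $= UP/GT$, accurate count $= TP/(TP+UP)$, complete
accuracy $= TP/(TP+UP+UN)$, all as percentages. Zero denominators yield
`NA` ("undefined"), never a silent zero that would corrupt fold averages.
Cross-fold aggregation normalizes counts per fold (a fold's summed TP over
its summed ground truth) before averaging; with a single fold the SD is
reported as 0. Per-image counts are exported for external statistics
(group comparisons such as ANOVA are out of scope here).

## The synthetic generator

`generate_scene()` emulates the imaging situation: a dark blue-stained
elliptical region on a lighter tongue surface; small darker Gaussian
speckle inside the stain imitating filiform papillae (the main distractor
class — something for the UP rate to fail on); 5–40 lighter, softly shaded
elliptical spots at integer centers (manual annotation clicks are
pixel-level) with configurable radius, eccentricity and contrast; a linear
illumination ramp; additive Gaussian noise. The default papilla count is a
truncated normal with mean 16.96 and SD 7.67 on $[5, 40]$, the count
distribution reported for the clinical cohort this pipeline targets. Spot
placement is rejection sampling inside the ellipse with a minimum
separation (9 px at 250; 8 px in the 128-px preset), erroring out when
infeasible rather than silently violating the constraint.

What the generator does **not** model: 3-D tongue curvature and focus
falloff, specular highlights, real stain color statistics, annotation
ambiguity (synthetic clicks are exact), and papilla shape diversity beyond
eccentric Gaussians. Passing tests on synthetic scenes therefore
demonstrate that the pipeline is self-consistent and trainable, not that
clinical-image accuracy is reproduced.

## Numerical choices and degenerate inputs

* Peak thresholds: relative 0.2, absolute floor 0.05, min distance 3 px —
  all config-exposed; the floor exists solely for near-empty prediction maps.
* Batch-norm $\epsilon = 10^{-5}$; running statistics with momentum 0.99;
  inference uses running statistics, so prediction is deterministic.
* Max-pool ties take the first element in scan order; peak ties the
  smaller row, then column — both deterministic.
* Assignment infeasibilities are encoded as a large finite cost ($10^9$),
  which makes "maximize cardinality, then minimize distance" a single
  minimization.
* Empty point sets, all-zero maps, zero-papilla scenes and empty masks all
  have defined behavior (empty set, empty set, all-zero target, Dice 1).
* Divergent training (non-finite loss) aborts with the epoch named rather
  than returning NaN weights.

## Limitations

The engine is CPU-only, double precision, and sized for desk-scale
experiments; full-width, full-resolution, 500-epoch training is possible
but slow. Batch size 2 makes batch-norm statistics noisy (a known property
of the protocol, not of this implementation). The stain detector assumes a
blue-dominant stain on a redder background; other dyes need different
`stain_channel_weights`. Synthetic-to-real transfer is untested by
construction — the package's claims are about pipeline correctness and
trainability, which is exactly what its test suite measures.
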