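---
title: "Few-shot prototype-guided vessel segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Few-shot prototype-guided vessel segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the episodic reformulation

Supervised vessel segmentation normally needs many densely annotated fundus
photographs. When only a handful of annotated images exist, the task can be
recast as few-shot semantic segmentation: every annotated image (every
"patient") is treated as its own class, and the overlapping patches cut from
that image are the class members. Patches from one retina are mutually far
more similar than patches across retinas, so a support/query structure
arises naturally: a C-way K-shot *episode* draws C classes, and per class K
*support* patches (with their annotations) plus K *query* patches whose
masks the model must infer. Training on a stream of such episodes teaches
the network to segment a new retina from only K annotated patches of it.

`fewvessel` implements this pipeline end to end: preprocessing, episode
construction, two trainable segmentation models, episodic optimisation,
confusion-matrix evaluation, and a pixel-wise model ensemble. Because no
deep-learning framework is available as an R dependency, the networks —
convolutions, pooling, bilinear resampling, non-local attention, the
reverse-mode gradients and the Adam optimiser — are implemented in the
package itself, with the dense kernels in compiled code (`src/ops.cpp`)
and a small autodiff tape in R. Gradient correctness is enforced by
central-finite-difference tests in the suite.

## Preprocessing

The chain is gamma correction (`out = in^gamma`, default `gamma = 1.2`,
a mild mid-tone compression common for fundus photographs), green-channel
separation (vessel contrast is strongest there), contrast-limited adaptive
histogram equalisation (CLAHE, default clip limit 2 on an 8x8 tile grid,
delegated to `EBImage::clahe`), and field-of-view masking. The literature
this package follows does not pin gamma or the CLAHE parameters, so both
are exposed as configuration with the defaults above. CLAHE runs on the
green plane (after channel separation), matching the usual panel order of
such pipelines; running it on the colour image before separation is the
main alternative reading and would change only the plane's contrast
statistics, not any interface.

Patches are square windows (default 224 px, stride 64, i.e. 160 px
overlap) with 0-based top-left origins and half-open extents. When the
image extent minus the template is not a multiple of the stride, one extra
border-flush origin is appended per axis so no tissue is dropped — needed
for whole-image evaluation; overlapping predictions are averaged
per pixel on reassembly, which round-trips unmodified patches exactly.
Binary masks are cropped by the same windows without resampling; when a
mask must be taken to a coarser feature grid it is bilinearly interpolated
and thresholded at 0.5 so it stays binary.

## The segmentation models

**Encoder.** The first four convolution blocks of a VGG16-style network
(ordinary 3x3 kernels — no dilation — ReLU, 2x2 max pooling), giving five
feature positions `l = 1..5`: the four block outputs before their pooling
plus the map after the fourth pooling, with spatial sides
`s, s/2, s/4, s/8, s/16` and widths `64, 128, 256, 512, 512`.

**Prototypes by mask average pooling.** At position `l`, a support patch's
feature map is multiplied elementwise by its (resized) vessel annotation
and summed over space, normalised by the *full* spatial area `W x H` — not
by the mask sum. The package implements exactly this form; it makes an
empty-vessel support yield a zero prototype rather than a division by
zero. K shots are merged by the element-wise mean, which also makes the
forward pass invariant to support order.

**Guidance.** A class prototype is applied to the query feature map as a
1x1 inner-product kernel (the prototype tiled over space and convolved),
yielding a single-channel similarity grid per position. This is the
standard realisation of "up-sample the prototype and convolve with the
query features"; cosine similarity is the obvious alternative and can be
swapped in behind the same interface.

**Baseline model.** Prototype and guidance at `l = 5` only; the guidance
grid is concatenated to the deepest query feature and decoded by the
reference decoder (four bilinear up-samplings interleaved with 3x3
convolutions of widths 512, 256, 256, 128, 128, 64, 64, 32, 3, 1; sigmoid
on the final logits).

**Upgraded model.** Prototypes at all five positions. At each decoder
stage, the up-sampled decoder state is concatenated with the
skip-connected query feature of the matching scale and that scale's
guidance grid ("gradual fusion" as channel concatenation — the minimal
reading; decoder input widths are widened just enough to accept the extra
channels, outputs unchanged). The deepest query feature first passes
through the MSA block: non-local attention (embedded-Gaussian affinities,
softmax-normalised over all positions, value aggregation, output
projection, residual add) at scales 1 and 2 (scale 2 via average pooling
and bilinear up-sampling), summed and mixed by a 1x1 convolution. The MSA
output feeds both the `l = 5` guidance and the decoder input; applying it
only to the guidance path is the alternative reading, with no interface
consequence. An ablation hook zeroes the `l < 5` guidance grids, reducing
the pass to a baseline-like one.

`channel_scale` multiplies every width (the final 3- and 1-channel output
convolutions excepted), leaving the architecture graph unchanged; the
desk-scale setting is 0.125. Weights are He-normal; no pretrained encoder
is used, so nothing needs downloading.

## Training

The loss is binary cross-entropy with a sigmoid link, averaged over the
pixels of each query prediction map and then over the C x K maps of the
episode — the per-map pixel mean keeps the loss patch-size invariant
while retaining the exact 1/(C·K) outer normalisation. Internally the loss
is computed from logits in the numerically stable form; the
probability-space form (with 1e-7 clamping) is exported and the two are
tested to agree. The optimiser is Adam. Production defaults are learning
rate 1e-4, 30 epochs of 100 episodes; one epoch is read as one hundred
sampled episodes. After each epoch the model is scored on fixed validation
episodes and the weights with the best validation *accuracy* are retained
(accuracy rather than loss — the quantity tracked per epoch in this
family of methods; the alternative is a one-line change). Query sets hold
K patches per class so the 1/(C·K) normalisation is exact over the
sampled maps.

At test time the held-out classes are unseen, so their queries are guided
by a fixed support set drawn once from the validation split and shared
across all test classes — the structural similarity of retinal vessels is
what makes a foreign support set informative.

## Synthetic phantoms

The generator emulates what the method needs from fundus data: dark
curvilinear branching structures (momentum random-walk centerlines,
trunk diameters up to ~10 px tapering to ~2 px, occasional child
branches) on a brighter low-frequency background (sum of a few random
low-frequency cosines) inside a circular field of view, with additive
Gaussian noise; masks are the exact rasterisation used to darken the
image, so ground truth is pixel-perfect. Geometry is seeded per
(seed, class) pair: patches within an image correlate, images differ —
exactly the property the episodic reformulation relies on. It does *not*
emulate optic disc, fovea, pathology, imaging artefacts, or the
inter-camera distribution shifts of real corpora; passing tests on
phantoms therefore demonstrate the correctness and trainability of the
pipeline, not clinical performance.

Desk-scale study conditions (used by the test-suite and the acceptance
script): 10 classes of 160 px images, 64 px patches at stride 48 (9
members per class), 3 training / 3 validation / 4 test classes, 3-way
3-shot episodes, `channel_scale` 0.125, 10 epochs of 20 episodes, learning
rate 1e-3. The raised learning rate suits the reduced-width network and
short schedule; the production default of 1e-4 is kept for full-width
training. The cross-domain ensemble experiment trains three members on
three synthetic domains that differ in vessel contrast, background level,
width range and noise, and fuses them on a fourth domain.

## Ensemble

Independently trained members each predict a probability map; a pixel is
voted vessel when strictly more than `T1` members exceed probability `T`
(strict inequalities exactly as in the printed indicator; defaults
`T = 0.5`, `T1 = floor(N1/2)`, i.e. 1 for three members — "at least 2 of
3"). Voted pixels take the maximum member probability, unvoted pixels the
minimum, so re-binarising the fused map at `T` reproduces the vote map —
a property the suite verifies on a million random triples alongside the
exhaustive 8-pattern truth table.

## Evaluation

Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy
`(tp+tn)/total` and F1 `2tp/(2tp+fn+fp)`, with strict `>` thresholding at
0.5 and field-of-view-restricted scoring by default (a flag scores all
pixels for parity with unmasked implementations). Zero-denominator
metrics are reported as NaN with a flag, never silently 0. AUC is the
tie-corrected Mann-Whitney statistic computed from midranks, verified
against O(n^2) pairwise enumeration. Split-level metrics pool counts
(micro-average); per-map metrics are also reported.

## Numerical and design notes

- Probabilities exactly at a threshold count as background everywhere
  (strict inequalities), so boundary behaviour is consistent between
  confusion counts and ensemble votes.
- Bilinear resampling uses half-pixel-centre coordinates with clamped
  edges; its adjoint is used for gradients.
- All randomness flows through explicit seeds; generation and sampling
  restore the caller's RNG state. Training under a fixed seed is
  bit-reproducible, and checkpoints restore predictions bit-identically.
- Degenerate inputs: constant planes pass CLAHE unchanged; empty support
  masks give zero prototypes (warning-free, well-defined); one-class AUC
  is NaN with a warning.
- The command-line interface is a thin installed Rscript
  (`inst/cli/fewvessel`) over the exported functions; the package
  functions are the primary interface.

## Limitations

Phantom results do not transfer claims to real public fundus corpora; the
full-width model at 224 px patches is implemented and shape-verified but
training it to convergence is a GPU-scale undertaking outside the test
suite's scope. The majority-vote ensemble is deliberately simple — learned
fusion is explicitly out of scope.
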