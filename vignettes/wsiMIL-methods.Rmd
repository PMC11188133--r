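---
title: "Attention-based MIL for whole-slide images: models, pipeline and design choices"
author: "wsiMIL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-based MIL for whole-slide images: models, pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsiMIL)
```

This vignette is the package's account of the science it implements: the
multiple-instance-learning (MIL) models and their assumptions, the training
protocol, the tile preprocessing pipeline, and the design decisions taken
where the method leaves choices open.

## The MIL setting

A whole-slide image is a bag $X = \{x_1, \dots, x_K\}$ of tiles with a
single binary label $Y$; tile labels $y_i$ exist conceptually but are never
observed. Under the standard MIL assumption,

$$Y = \begin{cases} 0 & \sum_k y_k = 0\\ 1 & \text{otherwise,}\end{cases}$$

a bag is positive iff it contains at least one positive instance (a
*witness*). Because instances carry no order, any valid bag classifier must
be permutation invariant; this is enforced structurally by pooling instances
with a softmax-normalized attention average rather than by any sequence
model. `bagLabelFromInstances()` implements the labeling rule; it is the
contract every synthetic bag is generated against and the property the
acceptance suite checks on a thousand random label vectors.

## The three heads

All heads factor as $g = p \circ a \circ f$. The feature extractor $f$ is
external to the models (see the embedding store below); the package's heads
consume embeddings $h_i = f(x_i)$.

**Attention module.** Each instance is scored independently,
$\psi_a(h_i) = w^\top \mathrm{act}(V h_i^\top)$, and scores are normalized
with a softmax over the bag's instances, $a_i = \mathrm{softmax}_i\,
\psi_a(h_i)$. `amil` and `hybrid` use $\mathrm{act} = \tanh$; `admil` uses a
leaky ReLU. The softmax subtracts the per-bag maximum before
exponentiating, so extreme logits cannot overflow.

**amil** pools the bag, $z = \sum_i a_i h_i$, and classifies the pooled
embedding with an MLP producing one positive-class logit; the probability is
its sigmoid, matching the binary cross-entropy loss.

**admil / hybrid** score each *attention-scaled* instance per class,
$S_i = \psi_p(a_i h_i) \in \mathbb{R}^2$, sum the per-instance scores into
bag class scores, and convert the two sums to a probability with a softmax.
The per-instance scores are signed patch contributions; the positive-class
score through a sigmoid is the *bounded contribution* in $(0,1)$, inhibitory
below $0.5$ and excitatory at or above it. The additive decomposition —
bag class scores equal the column sums of per-instance scores, exactly, in
the same accumulation order — is asserted by the test suite on every
architecture variant.

One notational point is genuinely ambiguous in the additive formulation:
$\psi_p(a_i(h_i))$ can be read as $\psi_p$ applied to the attention-scaled
embedding $a_i \cdot h_i$ or to the scalar weight. We implement the former
(the patch classifier sees each embedding multiplied by its attention
score), which keeps $\psi_p$'s input width equal to the embedding dimension
and matches the architecture diagrams of additive-MIL implementations.

**Widths.** The attention hidden width defaults to $L = 128$ and the
predictor to one ReLU hidden layer of 256 units; neither is prescribed by
the method, both are configurable (`milModel()`), and the defaults are small
enough to train on one CPU. The leaky-ReLU slope defaults to 0.01, the
common default. Weights are Glorot-uniform, biases zero, all seeded.

## Training and evaluation protocol

`trainModel()` implements the full protocol: a stratified 80/20 train/test
split, stratified 5-fold cross-validation on the training split with one
freshly initialized model per fold, selection of the fold with the best
validation AUROC (ties break toward the lowest fold index), and evaluation
of the selected model on the held-out test set. `repeatRuns()` repeats this
with consecutive master seeds and reports mean ± sd test AUROC; the sample
(n−1) standard deviation is used. The loss is the binary cross-entropy of
the positive-class probability (probabilities clamped to
$[10^{-7}, 1-10^{-7}]$ before the logs), optimized with Adam
(default learning rate $10^{-4}$, 50 epochs, 8 bags per step) and an
optional cosine-annealing schedule over the steps of one fit. Bags of
different sizes are handled by stacking their instances and reducing per
bag — no padding — so a batch is processed in a handful of matrix
operations; gradients are analytic (verified against finite differences in
the test suite) and accumulate in double precision. Training aborts with a
diagnostic on a non-finite loss; there is no other early stopping.

AUROC is computed rank-based with ties counted $1/2$ (the normalized
Mann–Whitney statistic); the test suite checks it against an all-pairs
brute-force oracle and against pROC.

## The synthetic bag generator

`generateBags()` instantiates the MIL assumption with the simplest structure
that makes witness localization measurable: negative instances are drawn
from an isotropic Gaussian at the origin, witnesses from an isotropic
Gaussian displaced by `separation` along a fixed unit direction
$u = \mathbf{1}/\sqrt{d}$, both with per-coordinate sd `noiseSd`. Every
positive bag receives $\lceil \text{witnessRate} \cdot K \rceil$ witnesses —
ceiling rounding guarantees at least one, so the labeling rule can never be
violated. Hidden instance labels travel in a side channel
(`hiddenInstanceLabels()`) that the training code never touches; only tests
and the acceptance script read it, to measure how much attention mass lands
on witnesses.

The benchmark conditions used throughout the acceptance suite are 200 bags
of 20 instances, $d = 32$, witness rate 0.2 and separation 3 (in noise-sd
units), five independent split seeds — a size chosen so the whole benchmark
trains all three architectures in a few CPU-minutes. Tumor fractions in
real slide cohorts vary widely (from "at least 90%" tumor content in some
archives to much more balanced distributions elsewhere), so the witness
rate is an exposed parameter rather than a constant.

What the generator does *not* emulate: correlated tiles, stain variation,
multi-scale structure, label noise, or any real H&E texture — passing the
benchmark shows the heads and protocol are implemented correctly and can
recover a planted witness signal, not that they reach any particular AUROC
on pathology data.

An observation worth recording: with these Gaussian bags the trained
leaky-ReLU attention (`admil`) ends up *less* concentrated (higher mean
attention entropy) than the trained tanh attention (`hybrid`), as measured
by the acceptance script's `attention_entropy_*` quantities. On real
histology embeddings the leaky-ReLU variant has been observed to produce
narrower attention; the reversal here is a property of this fixture — tanh
bounds the attention logits but back-propagates through every unit, while
the 0.01 negative slope of the leaky ReLU freezes roughly half of the
attention units, slowing concentration on an isotropic task with no
dominant embedding directions. The regression test encoding the
narrower-leaky ordering therefore fails on this fixture, and we have left
it failing rather than encode the opposite of the documented behavior of
the models on tissue.

## The preprocessing pipeline

`prepSlide()` reproduces the tile-fetching pipeline at thumbnail level:

1. **Thumbnail**: block-mean downsampling by the smallest power of two that
   brings the longest side to at most 1024 px (deterministic, unlike
   interpolating resizers).
2. **Tissue mask**: luminance grayscale, Otsu threshold, tissue = pixels
   *below* the threshold (tissue is darker than glass), then a binary
   closing with a disk of radius 2 px to fill pinholes and remove speckle.
   A constant image has no Otsu threshold and yields an empty mask with a
   warning.
3. **Artifact filter**: every tissue pixel's RGB color is compared with the
   mean color of the tissue pixel set; pixels farther than
   `colorDistanceThreshold` (default 60 RGB units) are dropped. The mean is
   computed once over the input set, not recomputed iteratively — the
   single-pass reading of the filter; an iterative variant would remove
   progressively more of a large artifact but also drift the mean.
4. **Coordinate mapping**: each surviving thumbnail pixel scales by the
   thumbnail-to-target downsample ratio to a half-open region at the target
   magnification; candidate tiles are the distinct 512-aligned tiles
   intersecting those regions. All coordinates are 0-based, half-open,
   (x = column, y = row), everywhere including the HDF5 store and manifests.
5. **Tissue-fraction filter**: a tile is kept iff the fraction of its
   $512^2$ footprint covered by surviving tissue pixels is at least
   `tissueFractionThreshold` (default 0.25); area outside the slide counts
   as non-tissue, and rejected tiles record the reason. The kept set equals
   an exhaustive brute-force rescan of every grid tile — asserted on
   synthetic slides in the acceptance suite.
6. **Sampling**: at 5x, when more than `tileCountLimit5x` (default 500)
   tiles survive, a uniform 60% sample is drawn; otherwise all tiles are
   used. For 10x/20x, parents at the previous magnification are K-means
   clustered (k-means++ initialization, Lloyd iterations capped at 25, all
   seeded — written here because `stats::kmeans` has no k-means++ option),
   at most 20 parents are sampled per cluster, and each parent expands to
   its 2×2 block of children by coordinate doubling, since each
   magnification step exactly doubles linear resolution. The clustering
   feature is the tile embedding vector (any numeric feature matrix is
   accepted; mean-RGB is the fallback when embeddings do not exist yet).

Edge tiles are padded to 512×512 with the mean color of the non-tissue
thumbnail pixels (white when the mask covers everything), content anchored
top-left. None of the thresholds is canonical; all live in `prepConfig()`
and are recorded with each run.

The synthetic slide generator (`generateSyntheticSlide()`) draws dark
tissue blobs on a light background with optional pen-colored strokes and
returns exact ground-truth tissue and artifact masks, which is what lets the
mask (IoU ≥ 0.95 against ground truth on the test fixtures) and the filters
be validated without slide archives. Blobs and strokes are not H&E texture;
they validate geometry and thresholds only.

## The embedding store

Tiles become embeddings through a `FeatureExtractor`: a named, deterministic
function from a 512×512 RGB tile to a fixed-length vector (1024 by default,
the length produced by common pathology feature extractors). Real trained
networks are external to this package; any of them can be registered behind
the same contract, which `validateExtractor()` checks once on a probe tile
(dimension and determinism). The shipped `toyFeatureExtractor()` — a frozen
random projection of 16×16 mean-pooled pixels through a tanh — exists so the
whole pipeline runs and is testable end to end.

Augmentation (`augmentTile()`) composes random HED stain perturbation
(Ruifrok–Johnston color deconvolution; per-channel scale in
$[1\pm\sigma]$, $\sigma = 0.05$, and shift in $[\pm 0.01]$ in stain-density
space), Gaussian pixel noise, a rotation from {90°, 180°, 270°} (or
identity) and independent horizontal/vertical flips, clipped to $[0, 255]$.
Two augmented replicas per tile is the default. Augmented embeddings are
stored separately from the originals, tagged by augmentation index, and are
intended as *extra training bags with the same label, never for
evaluation* — how augmentations enter training is not prescribed by the
protocol, so this choice is deliberately conservative and explicit.

`writeBags()`/`readBags()` persist bags to HDF5: per bag group,
`embeddings` (n × d float32), `coords` (n × 2 int64), optional
`aug/<k>/embeddings`, group attributes `label`, `magnification`, `mpp`,
`slide_type`, `config_hash`, and an optional `instance_labels` dataset
flagged `test_only`. float32 on disk keeps a 512×512×3 tile (786,432 bytes)
at 192× the size of its 1024-float32 embedding (4,096 bytes) — the reason
slide archives are stored in feature space. Reads validate the schema and
name any missing dataset; a write–read–write cycle is bit-exact on the
float32 payloads.

## Heatmaps

`scoresToGrid()` inverts the coordinate mapping: each tile's footprint at
thumbnail resolution is filled with its score, overlaps resolve by the mean
(the natural rule when children tile a parent), untouched pixels are
no-data. Attention overlays min–max normalize per slide before the colormap
— raw attention weights scale with bag size (they sum to 1 over $n$
instances), so absolute values are not comparable across slides; the
normalization can be disabled. The default colormap is viridis
(perceptually uniform); a constant grid maps to the colormap midpoint.
Contribution overlays are strictly two-colored: red for bounded scores in
$[0.5, 1)$ — the boundary 0.5 is excitatory — and blue for $(0, 0.5)$;
scores outside $(0, 1)$ are errors, never clipped. Rendering is pure:
identical inputs produce byte-identical PNGs.

## Numerical policy and degenerate inputs

* Softmax (attention and class link) always subtracts the maximum.
* BCE clamps probabilities at $\varepsilon = 10^{-7}$.
* All accumulation is in double precision; float32 only on disk.
* Fold selection ties break to the lowest fold index; `which.max` semantics.
* Empty instance-label vectors, empty pixel sets, constant images,
  single-class AUROC inputs, out-of-bounds tile origins and mismatched
  dimensions raise errors or warnings with specific messages rather than
  propagating NaNs.

## Known limitations

* The synthetic benchmark is far easier than slide classification; AUROC
  numbers on it say nothing about tissue data.
* The attention-entropy ordering between tanh and leaky-ReLU attention is
  fixture-dependent (see above).
* The preprocessing pipeline reads plain raster images (PNG/TIFF) and
  treats a provided image as one pyramid level; proprietary scanner formats
  need conversion upstream.
* No gated attention, transformers, multi-scale fusion, stain
  normalization, or instance-level supervision — deliberately out of scope.
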