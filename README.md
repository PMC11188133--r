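# wsiMIL

Attention-based multiple instance learning (MIL) for whole-slide-image (WSI)
classification and region-of-interest (RoI) discovery, in R.

## The problem

Digital pathology slides are scanned as image pyramids whose base resolution
is on the order of 100,000 × 100,000 px, while diagnostic labels (tumor
present, gene mutated) exist only at the slide or patient level. Supervised
tile-level learning is therefore impossible without costly expert
annotation. MIL sidesteps this: a slide is a *bag* of tiles (*instances*),
only the bag carries a label, and under the standard MIL assumption

```
Y = 0  if  Σ_k y_k = 0,   1 otherwise
```

a slide is positive iff at least one tile is positive. The tiles that drive
a positive prediction are candidate RoIs — a form of "virtual staining" that
makes the classifier interpretable to a pathologist.

## The models

All three heads share the pipeline `g = p ∘ a ∘ f`: a feature extractor `f`
maps each tile `x_i` to an embedding `h_i`; an attention module `a` scores
instances independently with `ψ_a(h_i) = wᵀ act(V h_iᵀ)` and normalizes the
scores with a softmax over the bag; a predictor `p` built on a small MLP
`ψ_p` produces the bag output.

| head | attention | predictor | link |
|---|---|---|---|
| `amil` | tanh | `ψ_p(Σ_i a_i h_i)`, one logit on the pooled embedding | sigmoid |
| `admil` | leaky ReLU | `Σ_i ψ_p(a_i h_i)`, per-class patch scores summed | softmax |
| `hybrid` | tanh | as `admil` | softmax |

The additive heads yield a per-patch, per-class contribution score; the
positive-class score passed through a sigmoid is the *bounded patch
contribution* in (0, 1), with values below 0.5 inhibitory (painted blue)
and values at or above 0.5 excitatory (painted red). All heads are
permutation invariant by construction.

Training follows the usual weakly supervised protocol: stratified 80/20
train/test split, 5-fold cross-validation on the training split, binary
cross-entropy loss, Adam (optional cosine annealing), selection of the fold
with the best validation AUROC, evaluation on the held-out test set, and
aggregation over five independent split seeds as mean ± sd AUROC.

The package also implements the surrounding tooling: a tile preprocessing
pipeline (Otsu tissue masking with morphological closing, artifact color
filtering, pyramid coordinate mapping, tile padding, tissue-fraction
filtering, fractional and K-means hierarchical sampling), an HDF5 embedding
store with HED stain augmentation behind a pluggable feature-extractor
interface, heatmap painting, and synthetic generators for MIL bags and
slide images so that everything is testable without any slide archive.

## Worked example

```r
library(wsiMIL)

## 60 synthetic bags: negative instances ~ N(0, I), witnesses shifted by
## 3 sd along a fixed direction; every positive bag has ceil(0.2 * 10) = 2
## witnesses among its 10 instances
bags <- generateBags(bagSimConfig(nBags = 60L, bagSizeRange = c(10L, 10L),
                                  witnessRate = 0.2, dim = 16L,
                                  separation = 3, seed = 11L))
bags
#> MILBagSet: 60 bags (30 positive / 30 negative), d = 16

cfg <- milTrainConfig(lr = 1e-3, epochs = 10L, kFolds = 3L, seed = 1L)
run <- trainModel("hybrid", bags, cfg)
run$foldMetrics
#>   fold valAuroc
#> 1    1 0.703125
#> 2    2 0.937500
#> 3    3 0.953125
run$selectedFold
#> [1] 3
run$testAuroc
#> [1] 0.8055556

pred <- predictBag(run$model, bags[[run$testIdx[1L]]])
pred
#> BagPrediction: P(positive) = 0.3753 over 10 instances, 2 excitatory patches
round(head(pred@bounded, 5), 3)
#> [1] 0.485 0.491 0.476 0.516 0.488
```

`run$foldMetrics` lists the validation AUROC of each cross-validation fold;
the fold-3 model (validation AUROC 0.95) is selected and reaches 0.81 AUROC
on the 12 held-out test bags (a small-sample illustration — the package
defaults train longer on more bags). `pred@bounded` holds the sigmoid-bounded
patch contributions of the first test bag: this bag is predicted negative
(P = 0.38) and most patches sit just below the 0.5 excitatory threshold.

Slide painting works the same way on any bag with tile coordinates:
`scoresToGrid()` rasterizes per-tile attention or bounded contributions onto
the thumbnail grid, `renderAttention()` / `renderContribution()` turn the
raster into an RGBA overlay, and `paintSlide()` composites it.

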