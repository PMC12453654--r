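---
title: "Majority clustering for imbalanced image classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Majority clustering for imbalanced image classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mciic)
```

## The model

A binary image dataset with a severe class imbalance (minority/majority
ratios of a few percent) biases ordinary classifiers toward the majority
class: overall accuracy stays high while minority recall — in screening
applications, the metric that matters — collapses. The method implemented
here assumes the majority class is *multi-modal*: it contains several
visually distinct subpopulations. Clustering the majority into `Nc` groups
and treating each group as its own class converts the binary problem into
an `(Nc+1)`-class problem whose per-class counts are much closer to the
minority count, so the minority class is no longer drowned out during
training. At evaluation time the `Nc` majority-cluster predictions are
folded back into a single negative label (`fold_to_binary()`), and the
confusion matrix is built with minority = positive.

The pipeline is: feature extraction → k-means on the majority features with
`Nc` chosen by the elbow criterion (`elbow_scan()`, `select_elbow_k()`) →
relabeling (`partition_majority()`) → `(Nc+1)`-way training with optional
class weighting (`train_classifier()`) → binary fold-back evaluation
(`evaluate_binary()`).

### The clustering objective and the elbow rule

k-means minimizes the within-cluster sum of squared errors
`SSE = Σᵢ ‖xᵢ − c_{a(i)}‖²` (squared Euclidean distance of every point to
its assigned centre). The implementation is Lloyd's algorithm with
distance-weighted greedy seeding (k-means++-style), `n_restarts = 10` keeping
the lowest SSE, convergence when the largest centre displacement falls below
`tol = 1e-4` in the original feature scale, and at most 300 iterations. An
emptied cluster is repaired by moving the point farthest from its assigned
centre into the empty cluster, which keeps `k` constant and strictly
decreases the objective, so Lloyd monotonicity is preserved; repair events
are counted on the returned model.

`elbow_scan()` fits every `k` in `1..cluster_n`. For each `k > 1` the best
`k−1` solution augmented with the farthest point is supplied as one extra
start, which makes the SSE curve non-increasing in `k` by construction —
without that nesting, restart noise can produce small upticks that confuse
elbow detection. The elbow itself is chosen by a deterministic geometric
rule: with both axes min-max normalized to `[0, 1]`, pick the `k` whose
point lies farthest (perpendicular distance) from the chord joining the
curve's endpoints. "The point where the decrease slows down" is otherwise a
qualitative instruction; the chord rule reproduces the visually obvious
elbow on curves with a sharp knee, is invariant to affine rescaling of the
SSE axis, and degrades gracefully (a linear or flat curve yields `k = 1`,
ties break to the smallest `k`).

### Class weighting

Both weighting schemes derive from one formula:
`wᵢ = total_samples / (nᵢ · n_classes)`, which satisfies `Σᵢ nᵢwᵢ = total`
exactly. The *weighted loss* uses the `wᵢ` directly as per-class
multipliers inside the cross-entropy objective, so minority
misclassification costs more. The *weighted augmentation sampler* converts
the weights to probabilities by normalizing by the maximum, which algebraically
reduces to `pᵢ = n_min / nᵢ`: the rarest class is always augmented
(`p = 1`), and counts (10, 20, 30) give probabilities (1, 0.5, 0.33 at two
decimals) — the only reading that reconciles the single weight formula with
those worked probabilities. Each epoch, a sample of class `i` is *replaced*
by an augmented copy with probability `pᵢ` (replacement rather than
oversampling keeps the epoch size fixed). The augmentation operators are
applied in the fixed order brightness (uniform factor in `[0.75, 1.25]`,
clipped to the pixel range) → rotation (uniform in `[−10°, +10°]`, bilinear
interpolation, edges filled with the nearest border value) → horizontal
flip with probability 0.5.

### Training and model selection

The trainer follows a fixed reference schedule: 50 epochs, SGD with
momentum 0.9 and weight decay 5e-4, batch size 256, initial learning rate
0.005 decayed ×0.1 every 12 epochs, cross-entropy loss with optional class
weights. After every epoch, validation predictions are folded to binary and
*binary* validation accuracy is computed; the returned weights come from
the epoch maximizing that binary accuracy (earliest epoch on ties). Binary
rather than multiclass accuracy is the governing selection criterion
because the multiclass labels are an artifact of preprocessing — two
majority clusters confused with each other are not an error the deployed
binary classifier ever makes.

The desk-scale implementation of the classifier contract is a multinomial
linear (softmax) model on the extracted features. The full-scale
alternative — fine-tuning a pretrained 18-layer residual network whose
penultimate layer provides 512 features — satisfies the same contract but
requires a deep-learning runtime and pretrained weights; this package
documents that contract (`make_backbone("deep18")` explains what is
missing) and does not ship it. All results in this package therefore use
the fallback extractor: bilinear resize to `side × side` grayscale,
flatten, per-image standardization to zero mean and unit population
variance. A constant image standardizes to the zero vector (the variance
guard uses a 1e-12 tolerance because bilinear resampling of a constant
image leaves ~1e-28 of floating-point variance, which naive division would
amplify into noise).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `cluster_n` | 8–10 | clusters | upper bound of the elbow scan; must exceed the plausible mode count, and the scan cost grows linearly in it |
| `n_restarts` | 10 | starts | k-means restarts per `k`; 10 suffices for global-optimum recovery on every enumerable test instance |
| `tol` | 1e-4 | feature units | Lloyd stopping threshold on centre displacement |
| split | 80/10/10 | fraction | train/validation/test, stratified per class, largest-remainder rounding with leftovers to train |
| `epochs`, `lr`, … | 50, 0.005, … | — | the reference schedule above |
| `brightness`, `rotation`, `flip_prob` | [0.75, 1.25], ±10°, 0.5 | — | the three augmentation operators |
| `backbone` | `fallback:16` | — | 256 features; tests often use `fallback:12` (144) for speed |

## The synthetic generator

`generate_imbalanced_images()` renders parametric grayscale patterns:
majority images cycle round-robin through `n_modes` Gaussian blobs placed
at distinct angles around the image centre (radius `side/4`, s.d.
`side/8`), minority images use a centred ring, and i.i.d. Gaussian pixel
noise (`noise_sd`, 0–255 scale) is added before rounding and clipping to
8-bit integers. Two design choices matter:

* patterns are parametric renderings, not natural-image statistics, so
  cluster separability is controlled by the single `noise_sd` knob — at
  `noise_sd = 6` on 24 px images the between-mode/within-mode separation
  ratio in fallback feature space is ≈13, comfortably in the
  well-separated regime the elbow-recovery checks assume;
* the minority ring is maximally distinct from every majority blob, so
  minority-versus-majority difficulty is governed *only* by the imbalance —
  the variable the method targets.

Default study conditions used by the directional comparison: imbalance 5%
(240 majority / 12 minority), 3 planted modes, `noise_sd = 10`, 24 px
images, fallback features at 12 px (144-d), 10 seeds. These sizes keep the
whole six-configuration suite around two seconds per seed while leaving the
baseline clearly pathological (it predicts majority everywhere), which is
the regime the method addresses.

What passing on these fixtures does **not** show: real chest X-rays have
majority modes that are overlapping, unbalanced in size and not Gaussian;
features from a pretrained deep network are not per-image-standardized
pixel grids; and real minority classes resemble majority modes far more
than a ring resembles a blob. The synthetic results validate the
*mechanics* (relabeling, fold-back, selection rules, weighting identities)
and the *direction* of the effect, not clinical performance numbers.

## Numerical choices and degenerate inputs

* Exactly balanced binary input: `partition_majority()` refuses and tells
  the caller to skip majority clustering — there is no majority.
* Minority identification is by count, never by class name.
* Imbalance ratios are rounded half-up to one decimal (2.2955… prints 2.3).
* Zero-denominator precision/recall/F1 report 0 and set a flag naming the
  metric, rather than NaN.
* Ties everywhere break deterministically: earliest epoch, smallest `k`,
  first cluster index.
* The elbow is computed on the training-split majority only. Running it on
  a test split would leak evaluation data into preprocessing; held-out
  splits are relabeled by nearest fitted centre (`relabel_with_model()`).
  A config override is deliberately *not* offered for test-split elbows.
* Clustering always uses deterministic (evaluation-mode) features; clusters
  smaller than `max(2, 0.5%)` of the majority produce a warning but are
  kept.

## Problem sizes

The test suite builds all fixtures in code at run time: enumerable k-means
instances at `n ≤ 8, d ≤ 2` (checked against an exhaustive-assignment
oracle and against an independent k-means implementation), elbow recovery
at 120 majority images × 20 seeds × mode counts 2–5, and the six-row
comparison at 252 images × 10 seeds. The full suite runs in about a minute
and a half on one CPU.

## Known limitations

* Only binary input tasks; multi-label and multi-class inputs are rejected.
* The deep backbone path is a documented contract, not shipped code.
* The elbow rule assumes a convex-ish SSE curve with one knee; curves with
  two comparable knees resolve to the stronger one, smallest `k` on ties.
* `weighted-aug` on top of majority clustering applies the per-class
  probabilities to the post-relabeling `(Nc+1)` classes (a config choice;
  the weights could alternatively be computed on the original binary
  counts, but the post-relabeling counts are what the weight formula's
  `num_classes` refers to once the transform has run).
* Augmentation of a near-balanced multiclass problem does little by
  construction (`pᵢ → 1` for all classes), which is the intended limit.
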