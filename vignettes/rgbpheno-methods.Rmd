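---
title: "Methods: image-based yield phenotyping on synthetic field trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based yield phenotyping on synthetic field trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgbpheno)
```

## The problem

In forage-grass breeding, thousands of individually spaced plants are scored
visually by an expert (an ordinal 0-5 "breeder's score", mostly a biomass
judgement) and, in calibration trials, harvested and weighed to obtain dry
matter yield (DMY, grams per plant). Aerial RGB imagery offers a cheap
alternative to both: one flight yields a per-plant image from which yield and
quality classes can be predicted. `rgbpheno` implements that analysis as a
reusable pipeline with three model framings:

1. **DMY regression** — predict grams from the plot image.
2. **Top-performers** — binary selection of the top 10% highest-yielding
   plants (`Select` vs `Discard`); the fraction is configurable.
3. **Breeder's score** — predict the score aggregated to three classes
   ({4,5} → class 1, {3} → class 2, {0,1,2} → class 3).

A benchmark linear model with the score as a categorical predictor — whose
prediction for score $s$ is the training-mean yield $\beta_s$ of score-$s$
plants — quantifies what the manual assessment alone achieves; image-based
models must beat it to justify themselves.

## The synthetic field generator

Because real UAV trials are expensive, every stage of the pipeline is
validated against a seeded generator ([generate_field()]) with known ground
truth. It emulates:

* **Layout.** A grid of square plots, one plant each, default
  44 families × 32 half-sib progeny × 3 replications = 4,224 plots.
* **Plants.** Each plant is a cluster of 3-40 overlapping green elliptical
  blobs (tillers) around the plot centre, with per-blob hue jitter inside a
  "plant green" HSV window (hue 95-145°, saturation 0.45-0.85, value
  0.17-0.80). The joint footprint of the blobs is the plant's true pixel
  area. A small share of blobs is dark enough to fall below the strict green
  counter's value floor, reproducing the slight under-count of conservative
  shade matching on dry or shaded tillers.
* **Soil.** Per-pixel Gaussian jitter around a mean soil colour plus a
  smooth field-wide brightness gradient, creating the intermediately light
  soil pixels that make broad green rules over-count.
* **Yield.** $\mathrm{DMY} = c\,A^{\gamma}(1+\varepsilon)$, with $A$ the true
  plant pixel area, allometric exponent $\gamma = 1.3$, coefficient
  $c = 0.025$ g, and $\varepsilon \sim N(0, 0.1)$ truncated so yield stays
  non-negative. With the default blob-size distributions this gives a
  right-skewed yield distribution with a mean around 40 g and a range of
  roughly 1-160 g, the scale typical of single-plant spaced trials.
* **Score.** The breeder's score is a noisy rank map:
  $s = \mathrm{clamp}(\mathrm{round}(5\hat F(\mathrm{DMY}) + \eta), 0, 5)$
  with $\hat F$ the (min-max scaled) empirical CDF and
  $\eta \sim N(0, \sigma_s)$. $\sigma_s$ continuously tunes the score's
  predictive power: at $\sigma_s = 0$ the benchmark model explains nearly
  all yield variance that a six-level rank discretisation can; as
  $\sigma_s \to \infty$ it explains none. The default
  $\sigma_s = 1.03$ was fixed once by running [calibrate_score_noise()]
  (bisection on the benchmark's held-out $R^2$) against a 1,008-plot
  reference field, landing the benchmark at $R^2 \approx 0.54$, the level
  an experienced breeder's visual assessment attains.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: perspective and stitching artefacts of real
orthomosaics, weeds and neighbouring-plant overlap, disease symptoms that
influence a real breeder's score beyond biomass, lighting/weather variation,
and 3-D canopy structure. Results on synthetic fields demonstrate that the
pipeline recovers known signal correctly, not that a given accuracy will be
reached in the field.

## The feature stack

[extract_features()] produces a named 542-entry descriptor:

| Block | Length | Notes |
|---|---|---|
| HSV colour histogram | 512 | 8×8×8 joint bins, hue-major flattening, L1-normalised |
| Hu moments | 7 | on the luminance image, `sign(h)·log10(|h|+1e-30)` scaling |
| Haralick texture | 13 | 32 grey levels, distance 1, symmetric GLCM, 4-direction average |
| Green counts | 2 | strict HSV shade box; broad band-ratio rule `G > 1.05·R, 1.05·B` |
| Vegetation indices | 8 | mean and population SD of RGBVI, GLI, VARI, NGRDI |

Choices that were genuinely open, and how they were settled:

* **Histogram space and bin count.** HSV with 8 bins per channel, following
  the common colour/shape/texture descriptor recipe; positions are 0-based
  (`hist_004` is the fifth bin). Both are configurable arguments.
* **"Predefined green shades".** Implemented as an HSV box — hue 70-170°,
  saturation ≥ 0.25, value ≥ 0.20 — which contains pure green and the
  generator's plant window while excluding typical soil. Thresholds are
  arguments of [green_count_strict()].
* **Broad counter margin.** 1.05 makes the band-ratio rule strictly contain
  the strict rule's plant pixels on generator imagery, preserving the
  intended under-/over-estimation bracket around true plant cover.
* **Vegetation-index aggregation.** Indices are computed per pixel and
  aggregated as mean and population SD. Pixels whose denominator magnitude
  is below $10^{-9}$ are excluded — VARI's denominator $G+R-B$ genuinely
  vanishes on some soil pixels; if every pixel is excluded the statistics
  are 0 with a warning.
* **Haralick parameterisation.** The conventional stable subset of 13
  statistics (not the rarely used 14th), 32 grey levels, distance 1, the
  four standard directions averaged after computing statistics per
  direction. The sum-variance statistic is centred on the sum average, the
  common corrected form. Degenerate denominators (constant images) yield 0.
* **Hu moments on intensity.** Computed on the luminance image rather than a
  binary plant mask, so no segmentation threshold leaks into the shape
  block; a constant image is defined to give the all-zero vector.

## Splits and responses

A stratified 10% test set is drawn first; the remaining 90% is split three
times into 80% train / 20% validation ([make_splits()]). Stratification uses
the three-class score by default; regression stratification uses DMY
quartile bins, since a continuous response has no natural strata. Per-stratum
counts use `round(frac · n)`, which keeps every partition within one record
of the global proportion. The three validation splits are drawn
independently by default (`shared_fold_seed` switches to one shared stream);
k-fold cross-validation is deliberately not the default because the
three-repeated-splits protocol is the one being reproduced.

Top-performer labels select exactly `ceiling(fraction · N)` plants — the
ceiling never under-selects candidates — with ties at the threshold resolved
towards earlier records so labelling is deterministic.

## The forest engine

The random-forest models are ensembles of CART trees grown by **rpart** on
bootstrap samples, each tree restricted to a random subspace of `mtry`
features (`sqrt(p)` for classification, `p/3` for regression). This engine
was built because no single installed forest implementation exposes the full
searched grid: Gini *and* entropy splitting, squared-error / Friedman /
absolute-error / Poisson-deviance regression criteria, depth limits, *and*
cost-complexity pruning. Friedman's improvement and the absolute-error
criterion are supplied as rpart user-written split methods (the
absolute-error splitter is $O(n^2)$ per node and intended for the moderate
node sizes used here); the others are rpart natives. The split semantics are
verified in the tests against closed-form impurity oracles
([node_criterion()]) on depth-1 stumps, and the regression forest is
cross-checked against an independent implementation (**ranger**).

Numerical conventions worth knowing:

* **Pruning scale.** `ccp_alpha` is expressed per observation and mapped to
  rpart's relative complexity parameter as
  `cp = ccp_alpha · n / deviance(root)`; 0.001 leaves trees essentially
  unpruned, 1 collapses them to the root. The searched grid is ten linearly
  spaced values on [0.001, 1] (log spacing available), matching the reading
  of "evenly spaced" under which the best-performing value 0.001 is the grid
  minimum either way.
* **Class weights.** "Balanced" assigns each observation of class $j$ the
  weight $N/(C\,n_j)$, computed on the full training response and applied to
  the bootstrap sample.
* **Selection metric and ties.** Grid search scores each cell by mean
  validation $R^2$ or balanced accuracy over the three splits; ties break
  towards the simpler model (smaller depth, stronger pruning, then listed
  criterion order).
* **MDI.** Importance sums each feature's primary-split criterion reduction
  over all trees and normalises to 1. Feature selection keeps features above
  the mean importance ($1/p$) or above the absolute 0.01 threshold; the top
  feature is always retained so the selection is never empty.
* **"Default" regression settings.** The tuned classification models use
  entropy, depth 7, alpha 0.001; the regression model's untuned setting is
  interpreted as 1000 trees, `p/3` features, unlimited depth, no pruning —
  all exposed as arguments.

## The CNN harness

The training protocol — replace the backbone's fully connected layers with a
task head (1, 2 or 3 outputs), train 15 epochs, report the best validation
epoch — is implemented around a compact three-conv-block backbone
(`tiny_test_net`: 3×3 convolutions with 8/16/32 channels, ReLU, 2×2 max
pooling, a 64-unit hidden dense layer), written in base R with im2col
matrix-multiply convolutions so the whole protocol runs in minutes on one
CPU. The four large published backbones are recognised configuration values
but require pretrained weights this package does not ship; requesting them
raises an error that points at `tiny_test_net`. With
`use_pretrained = TRUE` the backbone is frozen at initialisation and only
the head trains, mirroring the frozen-feature transfer regime.

Losses are the mean squared error for regression and a class-weighted
cross-entropy for classification, normalised by the summed weights (a
weighted mean — unit weights recover the ordinary cross-entropy, and the
normalisation changes no argmin). Probabilities below $10^{-12}$ at the true
class are clamped with a warning. Optimiser settings (Adam, batch 32,
learning rate $10^{-3}$) and the bilinear resize to a 32×32 input with
per-channel training-set standardisation are configuration values; none are
tuned by the harness itself. Backpropagation is verified against numerical
gradients in the tests.

## Evaluation

[evaluate_predictions()] computes, from scratch and verified against
brute-force oracles in the tests: $R^2$ (can be negative; undefined and an
explicit error when the observed values have zero variance) and RMSE in
grams for regression; the confusion matrix (raw and row-normalised),
one-vs-rest precision/recall/specificity (zero denominators yield 0,
flagged), balanced accuracy (mean per-class recall; an error if a true
class is absent, except inside task reports where the present-class mean is
used with a warning), $F_2$ with `Select` positive for the top task, and
macro-averaged $F_1$ over the three score classes. Macro averaging was
chosen for the single reported $F_1$; micro/weighted variants are a flag.
Entropy and cross-entropy use natural logarithms throughout; the base
affects no comparison or argmin.

## Problem sizes used in tests and the acceptance script

Synthetic validation runs use fields of roughly 100-500 plots and forests
of 150-300 trees — sizes chosen so the full suite exercises every stage,
including ten-replicate stability checks, in a few minutes while leaving
the statistical conclusions unchanged; the single full-size 4,224-plot
generation checks the trial layout arithmetic. The production default of
1000 trees is exercised in the reproducibility test.

## Known limitations

* The forest uses per-tree feature subspaces rather than per-node feature
  sampling; with many strongly collinear features (histogram bins, green
  counts, index means all track plant area) MDI credit is shared across the
  collinear group, as it is in any impurity-based importance.
* The absolute-error split criterion assumes unit weights and quadratic
  node cost; it is not intended for large nodes.
* The generator's breeder score depends on yield rank only; real scores
  also reflect disease and morphology, so the benchmark model's ceiling on
  real data may differ from the calibrated synthetic one.
* Orthomosaic construction, georeferencing and manual clip refinement are
  out of scope; layouts must be supplied (or generated) explicitly.
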