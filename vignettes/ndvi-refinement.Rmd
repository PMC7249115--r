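---
title: "Refining mixed-pixel satellite NDVI of row crops with a UAV-derived reference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining mixed-pixel satellite NDVI of row crops with a UAV-derived reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarefynet)
```

## The problem

Decametric satellite rasters (10 m cells, the scale of Sentinel-2 bands 4
and 8) are attractive for crop monitoring because they are free and
frequent, but in crops grown by rows — vineyards, orchards — every cell
mixes the radiometry of the canopy with that of the inter-row soil and weed
cover. The NDVI of such a *mixed pixel* is biased low relative to the
canopy's true vigor, and the bias varies from cell to cell with the local
canopy cover fraction. A single high-resolution UAV survey, reduced to a
canopy-only NDVI raster at the satellite grid, measures what the satellite
*should* have seen; this package learns the cell-wise correction from that
one reference acquisition and then applies it to satellite rasters from any
other date.

## The model

Each raster cell $x_i$ is presented to the network as a $3 \times 3 \times
2$ tensor: the first layer is the $3 \times 3$ NDVI neighborhood of the
cell (zero-padded at raster borders), the second the row-major linear
indices of those cells, scaled into $[0, 1]$. The location layer lets the
network associate a *position-specific* correction with each cell — exactly
what a cell-wise canopy-cover bias requires — while the NDVI layer carries
the radiometric context.

The regression $\hat y_i = F(X^{(i)}, \Theta)$ is a small residual
inception network:

* **Two inception blocks**, each with four parallel branches over the
  $3 \times 3$ field: a $1 \times 1$ convolution; a $1 \times 1$
  channel-halving convolution followed by a $3 \times 3$ convolution; the
  same with dilation rate 2 (an atrous convolution, reaching the patch
  corners); and a $3 \times 3$ average pool followed by a $1 \times 1$
  projection. Every branch ends with batch normalization and an ELU
  activation before channel concatenation. Zero padding keeps every branch
  output $3 \times 3$. The first block produces 8 maps per branch (32
  concatenated), the second 32 per branch (128 concatenated).
* **Head**: global average pooling, a dense layer of 32 ELU units, dropout
  ($p = 0.2$), and a single ELU unit.
* **Residual connection**: the raw central NDVI value is added to the head
  output, so the convolutional part only learns the *correction*, not the
  value. A final single ReLU unit ($y = \max(0, w s + b)$) absorbs any
  systematic offset between the satellite and UAV radiometric spaces and
  clips physically meaningless negative output.

The reference configuration has 17,145 trainable parameters (weights,
biases and batch-norm scale/shift; the hand tally is reproduced in the test
suite). The sources that describe this architecture class leave the exact
per-branch filter/dilation assignment open; the layout above is the classic
inception arrangement — the $1 \times 1$ halving convolution placed before
each spatial convolution — chosen because it is the smallest standard
configuration consistent with the stated per-branch widths, and it lands in
the published order of magnitude (about 16k parameters). All branch specs
are arguments of `rarefynet_config()`, so other assignments can be
explored.

Because convolutions on a fixed $3 \times 3$ field reduce to a gather plus
one matrix multiplication, the whole network is implemented in vectorized
base R with BLAS doing the arithmetic; a mini-batch forward/backward pass
is a handful of matrix products, and a desk-scale training run takes a few
minutes on one CPU core.

## Training

Training pairs each valid cell of the satellite raster with the reference
value of the UAV-derived canopy raster. The RMSE loss
$\mathcal{L} = \sqrt{\tfrac 1 m \sum_i (\hat y^{(i)} - y^{(i)})^2}$
is minimized by mini-batch AdamW — Adam with bias-corrected moments plus
*decoupled* weight decay $\Theta \leftarrow \Theta - \eta\, \hat m /
(\sqrt{\hat v} + \epsilon) - \eta \alpha \Theta$ — at a constant learning
rate for a fixed number of epochs. Defaults (all in `train_config()`):

| parameter | default | note |
|---|---|---|
| epochs | 300 | fixed budget, no early stopping (best-test checkpoint kept) |
| batch size $m$ | 64 | |
| learning rate $\eta$ | $5 \times 10^{-4}$ | constant; no schedule |
| weight decay $\alpha$ | $10^{-4}$ | unpublished upstream; a typical value for networks of this size |
| test fraction | 0.30 | random cell split (a row-blocked option exists) |
| ring rotations | 7 | see below |

**Augmentation.** Keeping the central pixel and the reference fixed, the 8
surrounding cells of both tensor layers are rotated cyclically around the
center, one ring position per step; the 7 nonzero rotations multiply the
training set by 8. Rotations are applied to the training partition only,
after splitting, so held-out cells are never seen in any orientation.

**Learning-rate range test.** `lr_range_test()` sweeps $\eta$
exponentially for one pass, smooths the per-step loss, and suggests the
rate one decade below the divergence point — the standard way to bound the
usable learning rate before committing to a constant one. On a quadratic
objective with curvature $c$ under plain gradient steps the suggestion
stays below the closed-form stability threshold $2/c$ (verified in the
tests). `hyperparameter_search()` implements the two-stage
random-then-grid search on a 10% subset for users who want to tune
$\eta$ and $\alpha$ jointly.

**Determinism.** Every stochastic element — initialization, shuffling,
dropout, splitting, clustering restarts, scene noise — draws from an
explicitly seeded generator through an internal RNG-preserving wrapper, so
identical seeds give bit-identical fits (single-threaded BLAS assumed) and
the user's RNG stream is never disturbed.

## Vigor zoning and validation

`kmeans_fit()` clusters the NDVI values of one map into $k = 3$ classes
with k-means++ seeding, 15 restarts, up to 500 Lloyd iterations and a
centroid-shift tolerance of $10^{-4}$, keeping the restart with the lowest
within-cluster sum of squares. Lloyd and Elkan share their fixed points —
Elkan is an acceleration, not a different estimator — so Lloyd is
implemented and its fixed-point property is cross-checked against
`stats::kmeans` in the tests. Ties go to the lowest class index; a cluster
emptied during iteration is re-seeded at the point farthest from its
assigned centroid. Classes are relabeled L/M/H in ascending centroid order,
and each map is clustered separately, so class boundaries are map-specific
by design.

`one_way_anova()` performs the textbook fixed-effects decomposition of
map pixels grouped by vigor class, with the upper-tail F p-value from
`stats::pf`; `pearson()` compares class maps encoded ordinally (L/M/H as
1/2/3 — the encoding is a documented choice, as correlation of categorical
maps requires one). `evaluate_refinement()` bundles RMSE, correlation and
the per-map ANOVA tables into one report.

## The synthetic scene generator

No raster from the original vineyard campaign is publicly deposited, so the
package ships a generator that reproduces the *statistical structure* the
method relies on, and the study conditions are its defaults
(`scene_config()`):

* 200 m × 200 m scene at 0.05 m GSD (the UAV survey scale), 10 m
  decametric cells — 400 cells, of which ~280 become training pairs, or
  ~2,240 tensors after augmentation: the same desk scale as a few-hectare
  vineyard study;
* parallel rows 2.5 m apart with a 1.0 m canopy band at a 15° azimuth
  (typical vineyard geometry; the azimuth avoids degenerate alignment of
  rows with cell edges, so canopy cover varies from cell to cell);
* a latent three-level vigor field: Gaussian noise on the decametric grid,
  smoothed with a 25 m kernel and tercile-thresholded, which yields smooth,
  spatially coherent vigor blocks with one level per cell;
* canopy NDVI levels 0.45 / 0.65 / 0.85 (σ = 0.05), soil 0.15 (σ = 0.03);
* the satellite raster is the all-pixel cell mean plus sensor noise
  (σ = 0.02) and a radiometric offset (−0.05), clipped to [−1, 1]; the
  reference raster is the canopy-only cell mean.

With all noise off, the satellite cell value is exactly
$f \cdot \bar y_{canopy} + (1 - f) \cdot \mu_{soil} + b$ for canopy
fraction $f$ — the mixed-pixel bias in closed form, which the tests verify
to $10^{-12}$ and which is precisely the signal the network must remove.
`generate_scene_pair()` draws a second scene with identical row geometry
but an independent vigor field, emulating a later acquisition date for the
temporal-transfer validation.

What the generator deliberately does **not** model: slope illumination and
shadows, atmospheric residues, phenological trajectories across dates,
co-registration error (a sub-cell shift option exists for sensitivity
checks), or non-Gaussian sensor noise. Passing the synthetic checks
therefore demonstrates that the estimator removes structured mixed-pixel
bias under realistic geometry and noise — not that any real scene is free
of the confounders above.

## Numerical choices and edge cases

* Locations are scaled by $1/(\text{pixel count} - 1)$ so both input
  layers share the unit range; raw indices are available via
  `normalize_locations = FALSE`. Out-of-raster neighbors are zero in both
  layers (the location 0 therefore collides with the first pixel's index —
  harmless in practice, and the padded NDVI layer disambiguates).
* Nodata: patches are extracted only for valid centers; invalid neighbors
  inside the raster are treated as padding. Refined rasters preserve the
  nodata mask; refined values above 1 are reported, not clipped.
* The final scalar unit is initialized at the identity ($w = 1$, $b = 0$),
  so the untrained model is the residual pass-through
  $\max(x_i, 0)$ and the initial loss equals the raw mixed-pixel error —
  a sensible starting point that also makes the residual path directly
  testable.
* Batch normalization uses batch statistics during training and running
  statistics (momentum 0.1) at inference; gradients flow through the batch
  statistics exactly (verified against numerical differentiation).
* A zero RMSE batch has zero gradient by convention (the loss is not
  differentiable at 0); training aborts with the last good checkpoint if
  the loss turns non-finite.
* Rasters travel as ESRI ASCII grids: a plain-text, GDAL-readable,
  georeferenced single-band format whose full-precision writer makes
  write/read round trips bit-exact — the natural choice for a package
  whose outputs must be reproducible to the bit.

## Known limitations

* The network corrects cells on the grid it was trained on (the location
  encoding is grid-specific); transferring across *dates* is supported and
  validated, transferring across *fields* is not.
* One-dimensional K-means with $k$ fixed at 3 is the zoning model; no
  spatial regularization is applied, and choosing $k$ is out of scope.
* The ANOVA treats pixels as independent observations, as is conventional
  in this validation design; spatial autocorrelation within vigor blocks
  makes its p-values optimistic on real data.

## Problem sizes used in the checks

The shipped tests train the reference architecture on the default 400-cell
scene pair (three seeds, 300 epochs each, a few minutes per run on one
core) for the headline refinement property, and use smaller scenes (40–60 m
at coarser GSD) for the exact structural identities, where size is
irrelevant. `scripts/acceptance.R` runs the full pipeline once at the
default scale for a given seed and writes every headline quantity as JSON.
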