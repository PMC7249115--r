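# rarefynet

Refinement of decametric satellite NDVI rasters of row crops using a single
high-resolution UAV-derived canopy reference.

## The problem

In crops grown by rows — vineyards, orchards — every ~10 m satellite pixel
blends canopy radiometry with inter-row soil and weed cover. The NDVI of
such a mixed pixel understates canopy vigor, and the bias varies cell by
cell with the local canopy cover, so raw decametric maps can fail to
separate vigor zones that an expert (or a UAV survey) sees clearly. Given
one co-registered, canopy-only NDVI raster derived from a UAV campaign,
this package trains a small convolutional network to undo that bias — and
the trained network then refines satellite rasters from *any* acquisition
date over the same field.

## The model

Each cell is presented as a 3×3×2 tensor: its 3×3 NDVI neighborhood
(zero-padded at borders) and the normalized row-major linear indices of
those cells. The regression

&nbsp;&nbsp;&nbsp;&nbsp;*ŷᵢ = F(X⁽ⁱ⁾, Θ)*

is a residual inception network: two inception blocks (four parallel
branches each — 1×1 conv; 1×1 halving + 3×3 conv; 1×1 halving + dilated
3×3 conv; 3×3 average pool + 1×1 projection — with batch-norm + ELU per
branch), global average pooling, a 32-unit dense layer with dropout
p = 0.2, and a single ELU unit whose output is **added to the raw central
pixel** before a final ReLU unit. The residual connection means the
convolutional part only learns the mixed-pixel *correction*; the final
affine ReLU unit absorbs radiometric offset between the satellite and UAV
NDVI spaces. 17,145 trainable parameters; training is mini-batch AdamW
(decoupled weight decay) on the RMSE loss, 300 epochs at a constant
learning rate 5e-4, with ring-rotation augmentation of the training
tensors. The network, its backpropagation and the optimizer are
implemented in vectorized base R (convolutions on a 3×3 field are a gather
plus one matrix product).

Also included: a k-means++/multi-restart K-means vigor classifier
(3 ordered classes L/M/H), one-way ANOVA and Pearson validation tools, a
synthetic vineyard scene generator (rows, soil, smooth 3-level vigor
field, canopy-masked and mixed-pixel downsampling) so the entire pipeline
runs without external data, and a command-line wrapper
(`inst/cli/rarefynet.R`) with `simulate / ndvi / train / refine / classify
/ validate / run-all` subcommands. Rasters travel as ESRI ASCII grids
(`.asc`, plain text, GDAL-compatible, bit-exact round trip).

## Worked example

```r
library(rarefynet)

# a synthetic vineyard: training scene + a later-date transfer scene
pair <- generate_scene_pair(scene_config(seed = 0))
uav  <- downsample_uav_reference(pair$train)   # canopy-only reference
sat  <- downsample_satellite_raw(pair$train)   # mixed-pixel satellite raster

fit <- rarefynet(sat, uav, train = train_config(epochs = 300, seed = 0))
print(fit)
#> NDVI refinement network (residual inception regression)
#>   grid: 20 x 20 cells; 280 train (+1960 augmented) / 120 test samples
#>   17145 trainable parameters, 300 epochs
#>   held-out RMSE vs reference: 0.0425 (raw satellite: 0.3451)
```

The held-out RMSE line is the headline: the raw satellite raster misses
the canopy reference by ~0.35 NDVI (the mixed-pixel bias plus noise); the
refined raster misses it by ~0.043 — a ~88% error reduction. Refining the
second scene (same row geometry, different vigor pattern — the analogue of
a later acquisition date) and validating against its true vigor field:

```r
sat2 <- downsample_satellite_raw(pair$transfer)
uav2 <- downsample_uav_reference(pair$transfer)
refined2 <- predict(fit, sat2)

report <- evaluate_refinement(sat2, refined2, uav2,
                              vigor_truth_map(pair$transfer))
report$metrics
#>  dataset       rmse   pearson
#>      raw 0.36352878 0.9582991
#>  refined 0.04270072 0.9660470
```

The ANOVA tables in `report$anova` show the same story: grouped by the
true vigor classes, the refined raster separates the class means more
strongly than the raw one (F = 2779 vs 2236 in this run, both at vanishing
p since the synthetic classes are well separated). `classify_vigor()`
turns any of the maps into an L/M/H management-zone raster.

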