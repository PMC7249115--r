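test_that("a noise-free scene takes exactly four distinct values", {
  cfg <- tiny_scene_config(seed = 5, sigma_canopy = 0, sigma_soil = 0)
  sc <- generate_scene(cfg)
  vals <- sort(unique(as.vector(sc$highres$values)))
  expect_equal(vals, sort(c(cfg$soil_mean, cfg$vigor_means)))
  # canopy pixels carry the level means, soil pixels the soil mean
  expect_true(all(sc$highres$values[!sc$canopy_mask] == cfg$soil_mean))
})

test_that("canopy cover matches the geometric area fraction", {
  cfg <- scene_config(size = c(40, 40), gsd = 0.05, cell = 10, seed = 2)
  sc <- generate_scene(cfg)
  expect_equal(mean(sc$canopy_mask), cfg$canopy_width / cfg$row_spacing,
               tolerance = 0.02)
  # rotated rows keep the same cover
  cfg2 <- scene_config(size = c(40, 40), gsd = 0.05, cell = 10,
                       row_azimuth = 37, seed = 2)
  expect_equal(mean(generate_scene(cfg2)$canopy_mask),
               cfg2$canopy_width / cfg2$row_spacing, tolerance = 0.02)
})

test_that("scene generation is deterministic and validated", {
  a <- generate_scene(tiny_scene_config(seed = 9))
  b <- generate_scene(tiny_scene_config(seed = 9))
  expect_identical(a$highres$values, b$highres$values)
  expect_identical(a$vigor_truth, b$vigor_truth)
  cc <- generate_scene(tiny_scene_config(seed = 10))
  expect_false(identical(a$highres$values, cc$highres$values))
  expect_setequal(unique(as.vector(a$vigor_truth)), 1:3)
  expect_error(scene_config(gsd = 10, cell = 10),
               class = "rarefynet_input_error")
  expect_error(scene_config(row_spacing = 1, canopy_width = 2),
               class = "rarefynet_input_error")
  expect_error(scene_config(gsd = 0.3, cell = 10),
               class = "rarefynet_input_error")
})

test_that("UAV-style downsampling averages canopy pixels only", {
  cfg <- tiny_scene_config(seed = 7, sigma_canopy = 0, sigma_soil = 0,
                           row_azimuth = 0)
  sc <- generate_scene(cfg)
  uav <- downsample_uav_reference(sc)
  # noise off and one vigor level per decametric cell: the cell mean is the
  # level mean, exactly
  expect_equal(uav$values, matrix(cfg$vigor_means[sc$vigor_truth],
                                  nrow(sc$vigor_truth)), tolerance = 1e-12)

  # with noise: per-cell mean over canopy pixels, against a direct oracle
  cfg2 <- tiny_scene_config(seed = 8)
  sc2 <- generate_scene(cfg2)
  uav2 <- downsample_uav_reference(sc2)
  f <- as.integer(cfg2$cell / cfg2$gsd)
  for (cell in list(c(1, 1), c(2, 3), c(4, 4))) {
    rows <- ((cell[1] - 1) * f + 1):(cell[1] * f)
    cols <- ((cell[2] - 1) * f + 1):(cell[2] * f)
    v <- sc2$highres$values[rows, cols]
    mk <- sc2$canopy_mask[rows, cols]
    expect_equal(uav2$values[cell[1], cell[2]], mean(v[mk]),
                 tolerance = 1e-12)
  }
})

test_that("cells straddling vigor levels average by canopy area", {
  # downsample at twice the vigor-block size so cells straddle blocks
  cfg <- tiny_scene_config(seed = 3, sigma_canopy = 0, sigma_soil = 0)
  sc <- generate_scene(cfg)
  uav20 <- downsample_uav_reference(sc, cell = 20)
  f <- as.integer(20 / cfg$gsd)
  v <- sc$highres$values[1:f, 1:f]
  mk <- sc$canopy_mask[1:f, 1:f]
  # area-weighted mean of the level means present in the cell
  lv <- v[mk]
  w <- table(lv)
  expect_equal(uav20$values[1, 1],
               sum(as.numeric(names(w)) * w) / sum(w), tolerance = 1e-12)
})

test_that("a cell with no canopy becomes nodata", {
  # rows 15 m apart with a 10 m grid and axis-aligned rows: some decametric
  # columns contain no canopy band
  cfg <- scene_config(size = c(30, 30), gsd = 0.25, cell = 10,
                      row_spacing = 15, canopy_width = 1, row_azimuth = 0,
                      sigma_canopy = 0, sigma_soil = 0, seed = 1)
  sc <- generate_scene(cfg)
  uav <- downsample_uav_reference(sc)
  col_has_canopy <- colSums(sc$canopy_mask) > 0
  f <- as.integer(cfg$cell / cfg$gsd)
  for (j in 1:3) {
    cols <- ((j - 1) * f + 1):(j * f)
    if (!any(col_has_canopy[cols])) expect_true(all(is.na(uav$values[, j])))
  }
  expect_true(any(is.na(uav$values)))
})

test_that("the mixed-pixel identity holds exactly with noise off", {
  cfg <- tiny_scene_config(seed = 4, sigma_canopy = 0, sigma_soil = 0,
                           sigma_sat = 0)
  sc <- generate_scene(cfg)
  raw <- downsample_satellite_raw(sc)
  uav <- downsample_uav_reference(sc)
  f <- as.integer(cfg$cell / cfg$gsd)
  frac <- rarefynet:::block_sum(sc$canopy_mask * 1, f) / f^2
  expected <- frac * uav$values + (1 - frac) * cfg$soil_mean + cfg$offset_sat
  expect_equal(raw$values, expected, tolerance = 1e-12)
  # equivalently: the raw-vs-reference gap is the mixed-pixel bias
  gap <- uav$values - raw$values
  expect_equal(gap, (1 - frac) * (uav$values - cfg$soil_mean) - cfg$offset_sat,
               tolerance = 1e-12)
  # soil dimmer than every canopy level and non-positive offset: the raw
  # map underestimates everywhere
  expect_true(all(raw$values < uav$values))
})

test_that("the radiometric offset shifts every cell exactly", {
  cfg0 <- tiny_scene_config(seed = 6, sigma_sat = 0, offset_sat = 0)
  cfgb <- tiny_scene_config(seed = 6, sigma_sat = 0, offset_sat = -0.05)
  r0 <- downsample_satellite_raw(generate_scene(cfg0))
  rb <- downsample_satellite_raw(generate_scene(cfgb))
  expect_equal(rb$values, r0$values - 0.05, tolerance = 1e-12)
})

test_that("K-means on the noise-free reference recovers the level means", {
  cfg <- tiny_scene_config(seed = 2, sigma_canopy = 0, sigma_soil = 0)
  sc <- generate_scene(cfg)
  uav <- downsample_uav_reference(sc)
  r <- kmeans_fit(as.vector(uav$values), seed = 1)
  expect_equal(r$centroids, cfg$vigor_means, tolerance = 1e-12)
  expect_equal(r$wcss, 0)
})

test_that("grid misregistration perturbs the satellite raster", {
  cfg <- tiny_scene_config(seed = 12, sigma_sat = 0)
  sc <- generate_scene(cfg)
  r0 <- downsample_satellite_raw(sc)
  r1 <- downsample_satellite_raw(sc, shift = c(1.25, 0))
  expect_false(identical(r0$values, r1$values))
  expect_identical(downsample_satellite_raw(sc, shift = 0)$values, r0$values)
  expect_error(downsample_satellite_raw(sc, shift = 12),
               class = "rarefynet_input_error")
})

test_that("scene pairs share geometry but not vigor arrangement", {
  pair <- generate_scene_pair(tiny_scene_config(seed = 1))
  expect_identical(pair$train$canopy_mask, pair$transfer$canopy_mask)
  expect_false(identical(pair$train$vigor_truth, pair$transfer$vigor_truth))
})
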