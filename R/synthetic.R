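# Synthetic vineyard scene generator.
#
# Emulates the statistical structure the refinement method assumes: a
# centimetric scene of parallel vine rows over inter-row soil, a spatially
# smooth three-level vigor field, a canopy-masked decametric "UAV reference"
# downsample, and a mixed-pixel decametric "raw satellite" downsample with
# additive sensor noise and a radiometric offset. Every quantity is
# deterministic given the seed, so the full pipeline is testable with no
# external data.

#' Scene configuration
#'
#' @param size scene extent in meters, length-2 (default 200 x 200).
#' @param gsd high-resolution ground sample distance in meters
#'   (default 0.05, i.e. 5 cm).
#' @param cell decametric cell size in meters (default 10); must be an
#'   integer multiple of `gsd` and larger than it.
#' @param row_spacing distance between row centerlines in meters
#'   (default 2.5).
#' @param canopy_width canopy band width in meters (default 1.0); must be
#'   smaller than `row_spacing`.
#' @param row_azimuth row direction in degrees from the y axis (default 15).
#' @param vigor_means canopy NDVI means of the low/medium/high vigor levels
#'   (default 0.45, 0.65, 0.85).
#' @param sigma_canopy per-pixel Gaussian noise of canopy NDVI
#'   (default 0.05).
#' @param soil_mean,sigma_soil inter-row soil NDVI mean and noise
#'   (defaults 0.15, 0.03).
#' @param sigma_sat satellite sensor noise added per decametric cell
#'   (default 0.02).
#' @param offset_sat satellite radiometric offset added per cell
#'   (default -0.05).
#' @param vigor_scale correlation length of the latent vigor field in
#'   meters (default 25): the white field is Gaussian-smoothed with this
#'   standard deviation before tercile thresholding, which yields smooth
#'   spatial vigor blocks.
#' @param seed integer RNG seed.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(size = c(200, 200), gsd = 0.05, cell = 10,
                         row_spacing = 2.5, canopy_width = 1.0,
                         row_azimuth = 15,
                         vigor_means = c(0.45, 0.65, 0.85),
                         sigma_canopy = 0.05,
                         soil_mean = 0.15, sigma_soil = 0.03,
                         sigma_sat = 0.02, offset_sat = -0.05,
                         vigor_scale = 25, seed = 1L) {
  if (length(size) == 1L) size <- c(size, size)
  if (gsd >= cell) stop_input("gsd must be smaller than the cell size")
  f <- cell / gsd
  if (abs(f - round(f)) > 1e-9)
    stop_input("cell size must be an integer multiple of gsd")
  if (canopy_width >= row_spacing)
    stop_input("canopy_width must be smaller than row_spacing")
  if (any(abs(c(vigor_means, soil_mean)) > 1))
    stop_input("NDVI means must lie in [-1, 1]")
  if (any(size %% cell != 0))
    stop_input("scene size must be a multiple of the cell size")
  structure(
    list(size = size, gsd = gsd, cell = cell, row_spacing = row_spacing,
         canopy_width = canopy_width, row_azimuth = row_azimuth,
         vigor_means = sort(vigor_means), sigma_canopy = sigma_canopy,
         soil_mean = soil_mean, sigma_soil = sigma_soil,
         sigma_sat = sigma_sat, offset_sat = offset_sat,
         vigor_scale = vigor_scale, seed = as.integer(seed)),
    class = "scene_config")
}

# Gaussian-smooth a matrix by separable weight matrices (rows renormalized,
# so edges are handled without wrap-around).
smooth_field <- function(z, sigma) {
  wmat <- function(n) {
    d <- outer(seq_len(n), seq_len(n), `-`)
    w <- exp(-d^2 / (2 * sigma^2))
    w / rowSums(w)
  }
  wmat(nrow(z)) %*% z %*% t(wmat(ncol(z)))
}

#' Generate a synthetic vineyard scene
#'
#' Rasterizes parallel canopy rows at the configured spacing and azimuth,
#' draws canopy pixels from the local vigor-level mean plus Gaussian noise
#' and soil pixels from the soil mean plus noise, and attaches the latent
#' three-level vigor field (tercile-thresholded smoothed Gaussian field at
#' decametric resolution).
#'
#' @param config a [scene_config].
#' @return a `vine_scene`: `highres` ([ndvi_map] at GSD), `canopy_mask`
#'   (logical matrix), `vigor_truth` (integer matrix of classes 1..3 at
#'   decametric resolution) and the `config`.
#' @export
generate_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  nr <- as.integer(round(config$size[2] / config$gsd))
  nc <- as.integer(round(config$size[1] / config$gsd))
  ncr <- as.integer(round(config$size[2] / config$cell))
  ncc <- as.integer(round(config$size[1] / config$cell))
  f <- as.integer(round(config$cell / config$gsd))
  with_seed(config$seed, {
    # latent vigor field on the decametric grid, smooth then terciles
    z <- smooth_field(matrix(stats::rnorm(ncr * ncc), ncr, ncc),
                      config$vigor_scale / config$cell)
    qs <- stats::quantile(z, c(1, 2) / 3)
    vigor <- matrix(1L + (z > qs[1]) + (z > qs[2]), ncr, ncc)
    # canopy geometry: distance across rows from the pixel center
    a <- config$row_azimuth * pi / 180
    xs <- (seq_len(nc) - 0.5) * config$gsd
    ys <- (seq_len(nr) - 0.5) * config$gsd
    u <- outer(-ys * sin(a), xs * cos(a), `+`)
    m <- u %% config$row_spacing
    mask <- abs(m - config$row_spacing / 2) < config$canopy_width / 2
    # NDVI: soil everywhere, canopy pixels overwritten from the local level
    vals <- config$soil_mean + stats::rnorm(nr * nc) * config$sigma_soil
    dim(vals) <- c(nr, nc)
    class_hi <- vigor[rep(seq_len(ncr), each = f),
                      rep(seq_len(ncc), each = f)]
    ncan <- sum(mask)
    vals[mask] <- config$vigor_means[class_hi[mask]] +
      stats::rnorm(ncan) * config$sigma_canopy
    vals[vals > 1] <- 1
    vals[vals < -1] <- -1
    structure(
      list(highres = ndvi_map(vals, pixel_size = config$gsd),
           canopy_mask = mask, vigor_truth = vigor, config = config),
      class = "vine_scene")
  })
}

#' @export
print.vine_scene <- function(x, ...) {
  cat(sprintf("<vine_scene> %g x %g m at %g m GSD (%d x %d px), canopy %.1f%%\n",
              x$config$size[1], x$config$size[2], x$config$gsd,
              nrow(x$highres$values), ncol(x$highres$values),
              100 * mean(x$canopy_mask)))
  invisible(x)
}

#' Canopy-only decametric reference (UAV-style downsampling)
#'
#' Per decametric cell, the mean NDVI over canopy-mask pixels only -- the
#' way a UAV survey is reduced to a canopy NDVI raster at the satellite's
#' resolution. Cells without canopy become nodata.
#'
#' @param scene a `vine_scene`.
#' @param cell target cell size in meters (default the scene's configured
#'   cell); must be an integer multiple of the GSD.
#' @return an [ndvi_map] at the decametric resolution.
#' @export
downsample_uav_reference <- function(scene, cell = scene$config$cell) {
  f <- cell / scene$config$gsd
  if (abs(f - round(f)) > 1e-9)
    stop_input("cell size must be an integer multiple of the scene gsd")
  f <- as.integer(round(f))
  v <- scene$highres$values
  msk <- scene$canopy_mask * 1
  s <- block_sum(v * msk, f)
  cnt <- block_sum(msk, f)
  out <- s / cnt
  out[cnt == 0] <- NA
  ndvi_map(out, pixel_size = cell, origin = scene$highres$origin)
}

#' Mixed-pixel decametric satellite raster
#'
#' Per decametric cell, the mean over all high-resolution pixels -- canopy
#' and inter-row soil alike -- plus Gaussian sensor noise and a radiometric
#' offset, clipped to \[-1, 1\]. This is the biased raster the refinement
#' network learns to correct: with all noise off, each cell equals
#' `fraction * canopy_mean + (1 - fraction) * soil_mean + offset`.
#'
#' @param scene a `vine_scene`.
#' @param cell target cell size (default the scene's configured cell).
#' @param seed RNG seed for the sensor noise (default derived from the
#'   scene seed, so the raster is a deterministic function of the scene).
#' @param shift optional x/y misregistration of the satellite sampling grid
#'   in meters (length 1 or 2, default 0): the grid is displaced by the
#'   nearest whole number of high-resolution pixels, with edge replication,
#'   to probe co-registration sensitivity.
#' @return an [ndvi_map] at the decametric resolution.
#' @export
downsample_satellite_raw <- function(scene, cell = scene$config$cell,
                                     seed = scene$config$seed + 1L,
                                     shift = c(0, 0)) {
  f <- cell / scene$config$gsd
  if (abs(f - round(f)) > 1e-9)
    stop_input("cell size must be an integer multiple of the scene gsd")
  f <- as.integer(round(f))
  v <- scene$highres$values
  if (length(shift) == 1L) shift <- c(shift, shift)
  if (any(shift != 0)) {
    px <- as.integer(round(shift / scene$config$gsd))
    if (any(abs(px) >= f)) stop_input("shift must stay below one cell")
    ridx <- pmin(pmax(seq_len(nrow(v)) + px[2], 1L), nrow(v))
    cidx <- pmin(pmax(seq_len(ncol(v)) + px[1], 1L), ncol(v))
    v <- v[ridx, cidx]
  }
  out <- block_sum(v, f) / f^2
  cfg <- scene$config
  if (cfg$sigma_sat > 0)
    out <- out + with_seed(seed, stats::rnorm(length(out))) * cfg$sigma_sat
  out <- out + cfg$offset_sat
  out[out > 1] <- 1
  out[out < -1] <- -1
  ndvi_map(out, pixel_size = cell, origin = scene$highres$origin)
}

#' Latent vigor field as a class map
#'
#' Wraps the scene's true decametric vigor field as a `vigor_map`, playing
#' the role of the expert in-field vigor survey when validating refined
#' rasters.
#'
#' @param scene a `vine_scene`.
#' @export
vigor_truth_map <- function(scene) {
  structure(
    list(classes = scene$vigor_truth, levels = c("L", "M", "H"),
         centroids = scene$config$vigor_means, kmeans = NULL,
         pixel_size = scene$config$cell, origin = scene$highres$origin),
    class = "vigor_map")
}

#' Generate a training scene and a transfer scene
#'
#' Two scenes with identical row geometry (the geometry is a deterministic
#' function of the configuration) but independently drawn vigor fields and
#' noise -- the synthetic analogue of training on one acquisition date and
#' refining another.
#'
#' @param config a [scene_config] for the training scene.
#' @param transfer_seed seed of the second scene (default `seed + 5000`).
#' @return list with scenes `train` and `transfer`.
#' @export
generate_scene_pair <- function(config = scene_config(),
                                transfer_seed = config$seed + 5000L) {
  cfg2 <- config
  cfg2$seed <- as.integer(transfer_seed)
  list(train = generate_scene(config), transfer = generate_scene(cfg2))
}
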