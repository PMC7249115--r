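# Patch-tensor extraction: every raster pixel is described to the network by
# a 3x3x2 tensor -- the 3x3 NDVI neighborhood (zero-filled outside the
# raster) plus a 3x3 layer of pixel-location values (row-major linear
# indices, scaled into [0, 1]). Patch cells are ordered row-major within the
# patch: position p in 1..9 corresponds to (row, col) offset
# ((p-1) %/% 3 - 1, (p-1) %% 3 - 1) from the center; the center is p = 5.

PATCH_OFFSETS <- cbind(dr = rep(-1:1, each = 3), dc = rep(-1:1, times = 3L))

# clockwise ring order around the center, as patch positions in 1..9
RING <- c(1L, 2L, 3L, 6L, 9L, 8L, 7L, 4L)

#' Extract the 3x3x2 input tensor for one pixel
#'
#' The first layer is the 3x3 NDVI patch centered on the pixel, zero-filled
#' where a neighbor falls outside the raster (zero padding) or holds nodata.
#' The second layer carries the 0-based row-major linear index of each cell,
#' scaled by `1 / (pixel_count - 1)` into \[0, 1\] when `normalize = TRUE`;
#' out-of-bounds cells carry location 0.
#'
#' @param map an [ndvi_map].
#' @param index 0-based row-major linear pixel index of the center.
#' @param normalize scale the location layer into \[0, 1\] (default `TRUE`).
#' @return a `patch_tensor`: list with 3x3 matrices `patch` and `locations`,
#'   and the `center_index`.
#' @export
extract_patch_tensor <- function(map, index, normalize = TRUE) {
  npix <- pixel_count(map)
  if (length(index) != 1L || index < 0 || index >= npix)
    stop_input("index must lie in [0, ", npix, ")")
  if (is.na(map$values[linear_to_rc(index, ncol(map$values))]))
    stop(errorCondition("center pixel is nodata: skip",
                        class = c("rarefynet_skip", "error")))
  b <- extract_patches(map, index, normalize = normalize)
  list2patch(b, 1L)
}

list2patch <- function(batch, i) {
  structure(
    list(patch = matrix(batch$patch[i, ], 3, 3, byrow = TRUE),
         locations = matrix(batch$loc[i, ], 3, 3, byrow = TRUE),
         center_index = batch$center[i]),
    class = "patch_tensor")
}

linear_to_rc <- function(idx, nc) {
  cbind(idx %/% nc + 1L, idx %% nc + 1L)  # 1-based matrix subscripts
}

# Vectorized patch extraction for many center pixels at once. Returns the
# flat representation used by the network: N x 9 matrices `patch` and `loc`
# (columns in patch position order), 0-based `center` indices and the center
# NDVI values `xc`.
extract_patches <- function(map, indices, normalize = TRUE) {
  v <- map$values
  nr <- nrow(v); nc <- ncol(v)
  npix <- nr * nc
  idx <- as.integer(indices)
  r <- idx %/% nc
  cc <- idx %% nc
  n <- length(idx)
  patch <- matrix(0, n, 9L)
  loc <- matrix(0, n, 9L)
  scale <- if (normalize && npix > 1L) 1 / (npix - 1) else 1
  for (p in 1:9) {
    r2 <- r + PATCH_OFFSETS[p, 1L]
    c2 <- cc + PATCH_OFFSETS[p, 2L]
    inb <- r2 >= 0L & r2 < nr & c2 >= 0L & c2 < nc
    val <- rep.int(0, n)
    val[inb] <- v[cbind(r2[inb] + 1L, c2[inb] + 1L)]
    val[is.na(val)] <- 0  # nodata neighbors treated as padding
    patch[, p] <- val
    loc[inb, p] <- (r2[inb] * nc + c2[inb]) * scale
  }
  list(patch = patch, loc = loc, center = idx, xc = patch[, 5L], n = n,
       npix = npix)
}

#' Pair a satellite raster with its UAV-derived reference
#'
#' Builds one training sample per grid cell valid in both maps: the 3x3x2
#' patch tensor from the satellite raster and the reference NDVI value from
#' the UAV-derived canopy raster. Samples are ordered row-major, so the
#' pairing is deterministic.
#'
#' @param sat satellite-driven [ndvi_map] (the raster to refine).
#' @param uav co-registered UAV-derived reference [ndvi_map].
#' @param normalize passed to the location-layer scaling
#'   (see [extract_patch_tensor]).
#' @return a `sample_set`: flat patch matrices plus the reference vector `y`.
#' @export
pair_datasets <- function(sat, uav, normalize = TRUE) {
  if (!is.ndvi_map(sat) || !is.ndvi_map(uav))
    stop_input("'sat' and 'uav' must be ndvi_map objects")
  if (!same_geometry(sat, uav))
    stop_input("satellite and reference rasters have different geometry")
  ok <- valid_mask(sat) & valid_mask(uav)
  # row-major 0-based indices of jointly valid cells, in row-major order
  nc <- ncol(sat$values)
  rc <- which(ok, arr.ind = TRUE)
  idx <- sort((rc[, 1] - 1L) * nc + (rc[, 2] - 1L))
  b <- extract_patches(sat, idx, normalize = normalize)
  yv <- t(uav$values)[idx + 1L]  # row-major linearization
  structure(
    list(patch = b$patch, loc = b$loc, center = b$center, xc = b$xc,
         y = as.numeric(yv), npix = b$npix, dim = dim(sat$values)),
    class = "sample_set")
}

#' @export
length.sample_set <- function(x) nrow(x$patch)

#' @export
`[.sample_set` <- function(x, i, ...) {
  structure(
    list(patch = x$patch[i, , drop = FALSE], loc = x$loc[i, , drop = FALSE],
         center = x$center[i], xc = x$xc[i],
         y = if (is.null(x$y)) NULL else x$y[i],
         npix = x$npix, dim = x$dim),
    class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %d samples from a %d x %d raster%s\n",
              length(x), x$dim[1], x$dim[2],
              if (is.null(x$y)) "" else " (with reference y)"))
  invisible(x)
}

rbind_sample_sets <- function(sets) {
  structure(
    list(patch = do.call(rbind, lapply(sets, `[[`, "patch")),
         loc = do.call(rbind, lapply(sets, `[[`, "loc")),
         center = unlist(lapply(sets, `[[`, "center")),
         xc = unlist(lapply(sets, `[[`, "xc")),
         y = if (is.null(sets[[1]]$y)) NULL else
           unlist(lapply(sets, `[[`, "y")),
         npix = sets[[1]]$npix, dim = sets[[1]]$dim),
    class = "sample_set")
}
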