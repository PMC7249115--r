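#' Georeferenced NDVI raster
#'
#' An `ndvi_map` is a single-band raster of normalized difference vegetation
#' index values on a regular grid. Valid values lie in \[-1, 1\]; nodata cells
#' are stored as `NA`. The georeferencing is a simple affine transform: the
#' coordinates of the lower-left corner and a square pixel size in meters.
#'
#' Pixels are addressed throughout the package by their 0-based row-major
#' linear index: pixel `(r, c)` (0-based, row 0 at the top of the grid) has
#' index `r * ncols + c`, ranging over `[0, pixel_count)`.
#'
#' @param values numeric matrix of NDVI values; `NA` marks nodata.
#' @param pixel_size pixel edge length in meters.
#' @param origin numeric length-2, x/y coordinates of the lower-left corner.
#' @return an object of class `ndvi_map` with fields `values`, `pixel_size`
#'   and `origin`.
#' @examples
#' m <- ndvi_map(matrix(runif(12, 0, 1), 3, 4), pixel_size = 10)
#' pixel_count(m)
#' @export
ndvi_map <- function(values, pixel_size = 1, origin = c(0, 0)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_input("'values' must be a numeric matrix")
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < -1 || max(v) > 1))
    stop_input("NDVI values must lie in [-1, 1]")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop_input("'pixel_size' must be a positive scalar")
  structure(
    list(values = values, pixel_size = as.numeric(pixel_size),
         origin = as.numeric(origin)),
    class = "ndvi_map")
}

#' @export
is.ndvi_map <- function(x) inherits(x, "ndvi_map")

#' @export
dim.ndvi_map <- function(x) dim(x$values)

#' Number of grid cells in a raster
#' @param map an [ndvi_map].
#' @export
pixel_count <- function(map) length(map$values)

#' Per-pixel validity mask
#' @param map an [ndvi_map].
#' @return logical matrix, `TRUE` where the pixel holds a valid NDVI value.
#' @export
valid_mask <- function(map) !is.na(map$values)

#' @export
print.ndvi_map <- function(x, ...) {
  d <- dim(x$values)
  nv <- sum(!is.na(x$values))
  cat(sprintf("<ndvi_map> %d x %d pixels (%.6g m), %d valid\n",
              d[1], d[2], x$pixel_size, nv))
  if (nv > 0)
    cat(sprintf("  NDVI range: [%.4f, %.4f]\n",
                min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$pixel_size, b$pixel_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Compute NDVI from red and near-infrared reflectance
#'
#' NDVI = (NIR - red) / (NIR + red). Cells where both bands are zero carry no
#' radiometric information and are set to nodata.
#'
#' @param red,nir co-registered reflectance matrices (values >= 0) or
#'   `ndvi_map`-like rasters holding reflectance.
#' @param pixel_size,origin georeferencing, used when `red`/`nir` are bare
#'   matrices.
#' @return an [ndvi_map].
#' @examples
#' compute_ndvi(matrix(0.1), matrix(0.3))$values  # 0.5
#' @export
compute_ndvi <- function(red, nir, pixel_size = 1, origin = c(0, 0)) {
  if (is.ndvi_map(red)) { pixel_size <- red$pixel_size; origin <- red$origin; red <- red$values }
  if (is.ndvi_map(nir)) nir <- nir$values
  if (!identical(dim(red), dim(nir)))
    stop_input("red and nir bands have different shapes")
  if (any(red < 0, na.rm = TRUE) || any(nir < 0, na.rm = TRUE))
    stop_input("reflectance must be non-negative")
  s <- nir + red
  out <- (nir - red) / s
  out[!is.na(s) & s == 0] <- NA
  ndvi_map(out, pixel_size = pixel_size, origin = origin)
}

#' Read / write NDVI rasters as ESRI ASCII grids
#'
#' Rasters are stored in the ESRI ASCII grid format (`.asc`): a six-line
#' header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by the grid values, top row first. Values are
#' written with full double precision, so a write/read round trip reproduces
#' the raster bit-exactly. The format is plain text and understood by GDAL,
#' QGIS and most GIS stacks.
#'
#' @param path file path.
#' @param map an [ndvi_map] to write.
#' @param nodata sentinel written for nodata cells (default -9999).
#' @return `read_ndvi_raster` returns an [ndvi_map]; `write_ndvi_raster`
#'   returns `path` invisibly.
#' @export
read_ndvi_raster <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  hdr <- list()
  for (i in 1:6) {
    ln <- strsplit(trimws(readLines(con, n = 1L)), "[[:space:]]+")[[1]]
    hdr[[tolower(ln[1])]] <- as.numeric(ln[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr)))
    stop_input("not an ESRI ASCII grid: missing header field(s) ",
               paste(setdiff(need, names(hdr)), collapse = ", "))
  vals <- scan(con, what = numeric(), quiet = TRUE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (length(vals) != nr * nc)
    stop_input("grid body has ", length(vals), " values, expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA
  ndvi_map(m, pixel_size = hdr$cellsize,
           origin = c(hdr$xllcorner, hdr$yllcorner))
}

#' @rdname read_ndvi_raster
#' @export
write_ndvi_raster <- function(map, path, nodata = -9999) {
  if (!is.ndvi_map(map)) stop_input("'map' must be an ndvi_map")
  v <- map$values
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.17g", map$origin[1]),
    sprintf("yllcorner %.17g", map$origin[2]),
    sprintf("cellsize %.17g", map$pixel_size),
    sprintf("NODATA_value %.17g", nodata))
  body <- apply(v, 1, function(row) paste(sprintf("%.17g", row), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
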