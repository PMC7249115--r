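# Three-class vigor zoning of NDVI maps by multi-restart K-means.
#
# Each NDVI map is clustered separately (class boundaries are map-specific
# by design, so low/medium/high always partitions the map at hand). Every
# restart seeds centroids with k-means++ and iterates Lloyd updates until
# the largest centroid shift drops below the tolerance; the restart with the
# lowest within-cluster sum of squares (WCSS) wins. Lloyd and Elkan iterate
# to identical fixed points -- Elkan is only an acceleration -- so Lloyd is
# used here and verified in the tests against an independent implementation.

#' Multi-restart K-means on NDVI values
#'
#' @param values numeric vector of NDVI values (NAs dropped).
#' @param k number of clusters (default 3: low/medium/high vigor).
#' @param n_init number of independent restarts (default 15).
#' @param max_iter maximum Lloyd iterations per restart (default 500).
#' @param tol convergence tolerance on the largest centroid shift
#'   (default 1e-4).
#' @param seed integer RNG seed; results are deterministic given the seed.
#' @return an object of class `vigor_kmeans`: ascending `centroids`,
#'   per-value `labels` (1..k, NA where the input was NA), `wcss`, `n_iter`,
#'   the winning `run_index`, the per-restart `wcss_all` and the winning
#'   run's per-iteration `wcss_trace`.
#' @export
kmeans_fit <- function(values, k = 3L, n_init = 15L, max_iter = 500L,
                       tol = 1e-4, seed = 1L) {
  x <- as.numeric(values)
  keep <- !is.na(x)
  xv <- x[keep]
  if (length(unique(xv)) < k)
    stop_input("need at least ", k, " distinct values, got ",
               length(unique(xv)))
  runs <- with_seed(seed, {
    lapply(seq_len(n_init), function(i) lloyd_once(xv, k, max_iter, tol))
  })
  wcss_all <- vapply(runs, `[[`, 1, "wcss")
  win <- which.min(wcss_all)
  r <- runs[[win]]
  # relabel so centroid(1) < centroid(2) < ... ; membership is unchanged
  ord <- order(r$centroids)
  relab <- integer(k)
  relab[ord] <- seq_len(k)
  labels <- rep(NA_integer_, length(x))
  labels[keep] <- relab[r$labels]
  structure(
    list(centroids = r$centroids[ord], labels = labels, wcss = r$wcss,
         n_iter = r$n_iter, run_index = win, wcss_all = wcss_all,
         wcss_trace = r$trace, k = k),
    class = "vigor_kmeans")
}

# one k-means++ seeded Lloyd run on a 1-D sample
lloyd_once <- function(x, k, max_iter, tol) {
  n <- length(x)
  # k-means++ seeding
  cen <- numeric(k)
  cen[1L] <- x[sample.int(n, 1L)]
  d2 <- (x - cen[1L])^2
  for (j in 2:k) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    cen[j] <- x[sample.int(n, 1L, prob = p)]
    d2 <- pmin(d2, (x - cen[j])^2)
  }
  trace <- numeric(0)
  lab <- assign_nearest(x, cen)
  for (it in seq_len(max_iter)) {
    # recompute centroids; an emptied cluster is re-seeded at the point
    # farthest from its currently assigned centroid
    newcen <- cen
    for (j in seq_len(k)) {
      m <- lab == j
      if (any(m)) {
        newcen[j] <- mean(x[m])
      } else {
        far <- which.max((x - cen[lab])^2)
        newcen[j] <- x[far]
      }
    }
    lab <- assign_nearest(x, newcen)
    trace <- c(trace, sum((x - newcen[lab])^2))
    shift <- max(abs(newcen - cen))
    cen <- newcen
    if (shift < tol) break
  }
  list(centroids = cen, labels = lab, wcss = sum((x - cen[lab])^2),
       n_iter = it, trace = trace)
}

# nearest centroid; equidistant points take the lowest centroid index
assign_nearest <- function(x, cen) {
  d <- outer(x, cen, function(a, b) (a - b)^2)
  max.col(-d, ties.method = "first")
}

#' @export
print.vigor_kmeans <- function(x, ...) {
  cat(sprintf("<vigor_kmeans> k=%d, wcss=%.6g (restart %d of %d, %d iter)\n",
              x$k, x$wcss, x$run_index, length(x$wcss_all), x$n_iter))
  cat("  centroids:", paste(sprintf("%.4f", x$centroids), collapse = ", "),
      "\n")
  invisible(x)
}

#' Classify an NDVI map into three ordered vigor classes
#'
#' Assigns every valid pixel to the nearest centroid of a K-means fit
#' (fitted on the map's own valid pixels when `result` is `NULL`), then
#' labels classes L/M/H in ascending centroid order. Nodata is preserved.
#'
#' @param map an [ndvi_map] with at least 3 distinct valid values.
#' @param result an existing [kmeans_fit] result to reuse, or `NULL`.
#' @param seed RNG seed for the fit when `result` is `NULL`.
#' @return a `vigor_map`: integer class raster (1=L, 2=M, 3=H, NA nodata)
#'   with the centroids and fit provenance attached.
#' @export
classify_vigor <- function(map, result = NULL, seed = 1L) {
  if (!is.ndvi_map(map)) stop_input("'map' must be an ndvi_map")
  vals <- map$values
  if (all(is.na(vals))) stop_input("map has no valid pixels")
  if (is.null(result))
    result <- kmeans_fit(as.vector(vals), seed = seed)
  if (!inherits(result, "vigor_kmeans")) stop_input("'result' must be a vigor_kmeans")
  classes <- matrix(NA_integer_, nrow(vals), ncol(vals))
  ok <- !is.na(vals)
  classes[ok] <- assign_nearest(vals[ok], result$centroids)
  structure(
    list(classes = classes, levels = c("L", "M", "H")[seq_len(result$k)],
         centroids = result$centroids, kmeans = result,
         pixel_size = map$pixel_size, origin = map$origin),
    class = "vigor_map")
}

#' @export
print.vigor_map <- function(x, ...) {
  tab <- table(factor(x$classes, levels = seq_along(x$levels),
                      labels = x$levels))
  cat(sprintf("<vigor_map> %d x %d cells\n", nrow(x$classes), ncol(x$classes)))
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = "  "), "\n")
  invisible(x)
}

#' @export
dim.vigor_map <- function(x) dim(x$classes)
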