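# Statistical validation of refined maps: one-way fixed-effects ANOVA of
# NDVI pixels grouped by vigor class, F-distribution p-values, Pearson
# correlation, and a combined refinement report.

#' One-way fixed-effects ANOVA
#'
#' Textbook decomposition for g groups of NDVI pixels:
#' `SS_classes = sum_j n_j (mean_j - mean)^2`,
#' `SS_error = sum_j sum_i (y_ij - mean_j)^2`, with degrees of freedom
#' `(g - 1, n - g)`; `F = MS_classes / MS_error`, p from the upper tail of
#' the F distribution. When all groups are internally constant
#' (`MS_error = 0`) F is `Inf` and p is 0.
#'
#' @param groups list of >= 2 non-empty numeric vectors (NAs dropped).
#' @return an `anova_table`: data.frame with rows Classes/Error/Total and
#'   columns `df`, `ss`, `ms`, `f`, `p`.
#' @export
one_way_anova <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2L) stop_input("need at least 2 groups")
  if (any(lengths(groups) < 1L)) stop_input("every group needs >= 1 observation")
  n <- sum(lengths(groups))
  g <- length(groups)
  if (n < g + 1L) stop_input("need at least ", g + 1L, " observations in total")
  all_vals <- unlist(groups, use.names = FALSE)
  gm <- mean(all_vals)
  means <- vapply(groups, mean, 1)
  nj <- lengths(groups)
  ss_c <- sum(nj * (means - gm)^2)
  ss_e <- sum(vapply(seq_len(g), function(j)
    sum((groups[[j]] - means[j])^2), 1))
  df_c <- g - 1L
  df_e <- n - g
  ms_c <- ss_c / df_c
  ms_e <- ss_e / df_e
  f <- if (ms_e == 0) Inf else ms_c / ms_e
  p <- f_pvalue(f, df_c, df_e)
  structure(
    data.frame(source = c("Classes", "Error", "Total"),
               df = c(df_c, df_e, df_c + df_e),
               ss = c(ss_c, ss_e, ss_c + ss_e),
               ms = c(ms_c, ms_e, NA_real_),
               f = c(f, NA_real_, NA_real_),
               p = c(p, NA_real_, NA_real_)),
    class = c("anova_table", "data.frame"))
}

#' @export
print.anova_table <- function(x, ...) {
  y <- x
  y$ss <- sprintf("%.4f", y$ss)
  y$ms <- ifelse(is.na(y$ms), "", sprintf("%.4f", y$ms))
  y$f <- ifelse(is.na(y$f), "", sprintf("%.4f", y$f))
  y$p <- vapply(y$p, function(p) {
    if (is.na(p)) "" else format(signif(p, 3), scientific = p < 1e-3)
  }, "")
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Upper-tail p-value of the F distribution
#'
#' @param f F statistic (>= 0; `Inf` gives 0).
#' @param df1,df2 numerator and denominator degrees of freedom (>= 1).
#' @export
f_pvalue <- function(f, df1, df2) {
  if (any(f < 0)) stop_input("F must be non-negative")
  if (any(c(df1, df2) < 1)) stop_input("degrees of freedom must be >= 1")
  ifelse(is.infinite(f), 0, stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Pearson product-moment correlation
#'
#' @param a,b equal-length numeric vectors (length >= 2) with non-zero
#'   variance.
#' @export
pearson <- function(a, b) {
  if (length(a) != length(b)) stop_input("inputs differ in length")
  if (length(a) < 2L) stop_input("need at least 2 observations")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop_input("correlation undefined: zero variance")
  stats::cor(a, b)
}

#' Assess a refinement against the UAV-derived reference
#'
#' Computes RMSE and Pearson correlation of the raw and refined satellite
#' rasters against the reference, and one-way ANOVA of each raster's pixels
#' grouped by the vigor classes -- the same comparisons used to judge
#' whether refinement recovers the agronomic signal the mixed pixels
#' obscured.
#'
#' @param raw,refined,reference co-registered [ndvi_map]s.
#' @param groups a `vigor_map` on the same grid defining the pixel grouping.
#' @return a `refinement_report`: `metrics` (data.frame of RMSE and r per
#'   dataset) and `anova` (named list of `anova_table`s for raw, refined and
#'   reference).
#' @export
evaluate_refinement <- function(raw, refined, reference, groups) {
  maps <- list(raw = raw, refined = refined, reference = reference)
  for (m in maps) if (!is.ndvi_map(m)) stop_input("inputs must be ndvi_map objects")
  if (!same_geometry(raw, refined) || !same_geometry(raw, reference))
    stop_input("rasters have different geometry")
  if (!inherits(groups, "vigor_map") ||
      !identical(dim(groups$classes), dim(raw$values)))
    stop_input("'groups' must be a vigor_map on the same grid")
  ok <- valid_mask(raw) & valid_mask(refined) & valid_mask(reference)
  metrics <- do.call(rbind, lapply(c("raw", "refined"), function(nm) {
    v <- maps[[nm]]$values[ok]
    r <- reference$values[ok]
    data.frame(dataset = nm, rmse = rmse_loss(v, r), pearson = pearson(v, r))
  }))
  anovas <- lapply(maps, function(m) {
    keep <- ok & !is.na(groups$classes)
    one_way_anova(split(m$values[keep], groups$classes[keep]))
  })
  structure(list(metrics = metrics, anova = anovas),
            class = "refinement_report")
}

#' @export
print.refinement_report <- function(x, ...) {
  cat("Refinement report (vs UAV-derived reference)\n")
  print(x$metrics, row.names = FALSE)
  for (nm in names(x$anova)) {
    cat("\nANOVA --", nm, "grouped by vigor class\n")
    print(x$anova[[nm]])
  }
  invisible(x)
}

#' Write a refinement report as CSV files
#'
#' @param report a `refinement_report`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  for (nm in names(report$anova))
    utils::write.csv(report$anova[[nm]],
                     file.path(dir, paste0("anova_", nm, ".csv")),
                     row.names = FALSE)
  invisible(dir)
}
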