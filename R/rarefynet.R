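#' Fit an NDVI refinement model
#'
#' Trains the residual inception network to map decametric satellite NDVI
#' patch tensors onto the co-registered UAV-derived canopy NDVI reference.
#' The workflow is: pair the two rasters cell by cell, split into train and
#' test partitions, augment the training partition by ring rotation, build
#' the network, and run mini-batch AdamW optimization of the RMSE loss for a
#' fixed number of epochs.
#'
#' Once fitted, the model refines a satellite raster from any acquisition
#' date over the same grid via [predict.rarefynet] / [refine_map]: the
#' mixed-pixel bias it learned from the single reference date transfers
#' across dates because the row/inter-row geometry, encoded by the patch
#' neighborhood and pixel locations, is stable.
#'
#' @param sat satellite-driven [ndvi_map] (training input).
#' @param uav co-registered UAV-derived canopy reference [ndvi_map].
#' @param config architecture configuration ([rarefynet_config]).
#' @param train training configuration ([train_config]).
#' @param blocked_split hold out whole raster rows instead of random cells.
#' @return an object of class `rarefynet` with components `model` (final
#'   parameters), `best` (best-test-loss checkpoint), `history`, `test`
#'   metrics on the held-out cells, and the data geometry. Methods:
#'   `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`.
#' @examples
#' \donttest{
#' sc <- generate_scene(scene_config(size = c(60, 60), gsd = 0.25, seed = 1))
#' uav <- downsample_uav_reference(sc)
#' sat <- downsample_satellite_raw(sc)
#' fit <- rarefynet(sat, uav, train = train_config(epochs = 30, seed = 1))
#' refined <- predict(fit, sat)
#' }
#' @export
rarefynet <- function(sat, uav, config = rarefynet_config(),
                      train = train_config(), blocked_split = FALSE) {
  pairs <- pair_datasets(sat, uav, normalize = config$normalize_locations)
  parts <- split_train_test(pairs, train$test_fraction, seed = train$seed,
                            blocked = blocked_split)
  aug <- augment_samples(parts$train, train$augmentation_rotations)
  model <- build_model(config, seed = train$seed)
  fit <- train_rarefynet(model, aug, parts$test, train)
  test_metrics <- NULL
  if (length(parts$test) > 0L) {
    yhat <- predict(fit$model, parts$test)
    test_metrics <- list(
      rmse = rmse_loss(yhat, parts$test$y),
      pearson = if (stats::sd(yhat) > 0 && stats::sd(parts$test$y) > 0)
        stats::cor(yhat, parts$test$y) else NA_real_,
      rmse_raw = rmse_loss(parts$test$xc, parts$test$y))
  }
  structure(
    list(model = fit$model, best = fit$best, history = fit$history,
         config = config, train = train,
         n_train = length(parts$train), n_train_augmented = length(aug),
         n_test = length(parts$test), test = test_metrics,
         parts = parts, sat = sat, uav = uav,
         call = match.call()),
    class = "rarefynet")
}

#' @export
print.rarefynet <- function(x, ...) {
  cat("NDVI refinement network (residual inception regression)\n")
  cat(sprintf("  grid: %d x %d cells; %d train (+%d augmented) / %d test samples\n",
              nrow(x$sat$values), ncol(x$sat$values),
              x$n_train, x$n_train_augmented - x$n_train, x$n_test))
  cat(sprintf("  %d trainable parameters, %d epochs\n",
              count_parameters(x$model), nrow(x$history)))
  if (!is.null(x$test))
    cat(sprintf("  held-out RMSE vs reference: %.4f (raw satellite: %.4f)\n",
                x$test$rmse, x$test$rmse_raw))
  invisible(x)
}

#' @export
summary.rarefynet <- function(object, ...) {
  print(object)
  h <- object$history
  if (nrow(h)) {
    cat(sprintf("  final train loss %.4f; best test loss %.4f (epoch %d)\n",
                h$train_loss[nrow(h)], min(h$test_loss, na.rm = TRUE),
                which.min(h$test_loss)))
  }
  invisible(object)
}

#' @export
coef.rarefynet <- function(object, ...) {
  unlist(object$model$params)
}

#' Refine a satellite NDVI raster with a trained model
#'
#' Extracts the patch tensor of every valid pixel, evaluates the network in
#' inference mode, and writes the refined value back on the same grid.
#' Nodata cells are preserved. Outputs are non-negative by the final ReLU
#' unit; values above 1 are not clipped but their count is reported via a
#' message.
#'
#' @param model a fitted `rarefynet` or a `rarefynet_model`.
#' @param sat [ndvi_map] to refine (same grid geometry family as training).
#' @return refined [ndvi_map].
#' @export
refine_map <- function(model, sat) {
  fit <- if (inherits(model, "rarefynet")) model$model else model
  if (!inherits(fit, "rarefynet_model")) stop_input("not a rarefynet model")
  if (!is.ndvi_map(sat)) stop_input("'sat' must be an ndvi_map")
  if (pixel_count(sat) < 1L) stop_input("raster has no pixels")
  ok <- valid_mask(sat)
  nc <- ncol(sat$values)
  rc <- which(ok, arr.ind = TRUE)
  if (nrow(rc) == 0L) stop_input("raster has no valid pixels")
  idx <- sort((rc[, 1] - 1L) * nc + (rc[, 2] - 1L))
  batch <- extract_patches(sat, idx,
                           normalize = fit$config$normalize_locations)
  yhat <- net_forward(fit, batch, training = FALSE, keep_cache = FALSE)$yhat
  over <- sum(yhat > 1)
  if (over > 0)
    message(over, " refined value(s) exceed 1 (left unclipped)")
  out <- matrix(NA_real_, nrow(sat$values), nc)
  out[cbind(idx %/% nc + 1L, idx %% nc + 1L)] <- yhat
  m <- sat
  m$values <- out
  m
}

#' Predict method for fitted refinement models
#'
#' @param object a fitted `rarefynet`.
#' @param newdata an [ndvi_map] (returns a refined map), a `sample_set` or a
#'   single `patch_tensor` (returns refined values). Defaults to the
#'   training satellite raster.
#' @param ... unused.
#' @export
predict.rarefynet <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$sat
  if (is.ndvi_map(newdata)) return(refine_map(object, newdata))
  predict(object$model, newdata)
}

#' @export
fitted.rarefynet <- function(object, ...) {
  predict(object$model, object$parts$train)
}

#' @export
residuals.rarefynet <- function(object, which = c("test", "train"), ...) {
  which <- match.arg(which)
  set <- object$parts[[which]]
  set$y - predict(object$model, set)
}

#' @export
plot.rarefynet <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) {
    warning("empty training history")
    return(invisible(x))
  }
  ylim <- range(c(h$train_loss, h$test_loss), na.rm = TRUE)
  graphics::plot(h$epoch, h$train_loss, type = "l", ylim = ylim,
                 xlab = "epoch", ylab = "RMSE loss", ...)
  if (any(is.finite(h$test_loss)))
    graphics::lines(h$epoch, h$test_loss, lty = 2)
  graphics::legend("topright", legend = c("train", "test"), lty = 1:2,
                   bty = "n")
  invisible(x)
}
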