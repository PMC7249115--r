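# Training machinery: RMSE loss, ring-rotation augmentation, the AdamW
# update, train/test splitting, a learning-rate range test, the mini-batch
# training loop and a random-then-grid hyperparameter search.

#' Training configuration
#'
#' @param epochs number of passes over the training set (default 300).
#' @param batch_size mini-batch size m (default 64).
#' @param learning_rate constant step size eta (default 5e-4); no schedule
#'   is applied.
#' @param weight_decay decoupled weight-decay coefficient alpha of the AdamW
#'   rule (default 1e-4).
#' @param beta1,beta2,eps Adam moment-decay rates and denominator floor.
#' @param augmentation_rotations number of ring rotations added per training
#'   sample, 0..7 (default 7: every nonzero cyclic shift of the 8-pixel
#'   ring).
#' @param test_fraction held-out fraction for the test partition
#'   (default 0.30).
#' @param seed integer driving every stochastic element (weight init,
#'   shuffling, dropout, splitting).
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 300L, batch_size = 64L,
                         learning_rate = 5e-4, weight_decay = 1e-4,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         augmentation_rotations = 7L, test_fraction = 0.30,
                         seed = 1L) {
  if (learning_rate <= 0) stop_input("learning_rate must be positive")
  if (test_fraction < 0 || test_fraction >= 1)
    stop_input("test_fraction must lie in [0, 1)")
  if (augmentation_rotations < 0L || augmentation_rotations > 7L)
    stop_input("augmentation_rotations must lie in 0..7")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 augmentation_rotations = as.integer(augmentation_rotations),
                 test_fraction = test_fraction, seed = as.integer(seed)),
            class = "train_config")
}

#' Root-mean-square error loss
#'
#' `L = sqrt(mean((prediction - reference)^2))`: the loss minimized during
#' training, weighting large errors more heavily than the mean absolute
#' error would.
#'
#' @param predictions,references equal-length numeric vectors, length >= 1.
#' @export
rmse_loss <- function(predictions, references) {
  if (length(predictions) == 0L) stop_input("empty input")
  if (length(predictions) != length(references))
    stop_input("predictions and references differ in length")
  sqrt(mean((predictions - references)^2))
}

# --- ring-rotation augmentation -------------------------------------------

rotate_ring_cols <- function(M, s) {
  # value at ring slot j comes from slot j - s (cyclically): one clockwise
  # step moves every ring pixel one position onward
  from <- RING[((seq_len(8L) - 1L - s) %% 8L) + 1L]
  M[, RING] <- M[, from, drop = FALSE]
  M
}

#' Augment samples by rotating the 8-pixel ring
#'
#' Keeping the central pixel and the reference value fixed, each training
#' sample yields up to 7 new ones by cyclically rotating the eight
#' surrounding pixels (both the NDVI layer and the location layer) around
#' the center. The returned set contains the originals first, then the
#' rotation blocks in step order.
#'
#' @param samples a `sample_set`.
#' @param n_rotations number of distinct nonzero cyclic steps, 0..7.
#' @return a `sample_set` of `(n_rotations + 1) * length(samples)` samples.
#' @export
augment_samples <- function(samples, n_rotations = 7L) {
  if (n_rotations < 0L || n_rotations > 7L)
    stop_input("n_rotations must lie in 0..7")
  if (n_rotations == 0L) return(samples)
  sets <- vector("list", n_rotations + 1L)
  sets[[1L]] <- samples
  for (s in seq_len(n_rotations)) {
    rot <- samples
    rot$patch <- rotate_ring_cols(samples$patch, s)
    rot$loc <- rotate_ring_cols(samples$loc, s)
    sets[[s + 1L]] <- rot
  }
  rbind_sample_sets(sets)
}

#' Augment a single sample pair
#'
#' @param pair list with a `patch_tensor` `x` and reference value `y`.
#' @param n_rotations number of rotations, 0..7.
#' @return list of `n_rotations + 1` pairs (the original first).
#' @export
augment_sample <- function(pair, n_rotations = 7L) {
  x <- pair$x
  set <- list(patch = matrix(as.vector(t(x$patch)), 1L, 9L),
              loc = matrix(as.vector(t(x$locations)), 1L, 9L),
              center = x$center_index, xc = x$patch[2L, 2L],
              y = pair$y, npix = NA_integer_, dim = c(NA_integer_, NA_integer_))
  class(set) <- "sample_set"
  aug <- augment_samples(set, n_rotations)
  lapply(seq_len(length(aug)), function(i) {
    list(x = list2patch(aug, i), y = aug$y[i])
  })
}

# --- AdamW -----------------------------------------------------------------

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

#' One AdamW update
#'
#' Adam with bias-corrected first/second moments plus decoupled weight
#' decay: `theta <- theta - eta * mhat / (sqrt(vhat) + eps) - eta * alpha *
#' theta`. With `alpha = 0` this is exactly plain Adam.
#'
#' @param params,grads named lists of numeric arrays with matching shapes.
#' @param state optimizer state from a previous call, or `NULL` to start at
#'   zero moments.
#' @param lr step size eta (> 0).
#' @param weight_decay decoupled decay coefficient alpha.
#' @param beta1,beta2,eps Adam constants.
#' @return list with updated `params` and `state`.
#' @export
adamw_step <- function(params, grads, state = NULL, lr = 5e-4,
                       weight_decay = 0, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  if (is.null(state)) state <- adamw_init(params)
  t <- state$t + 1L
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) g <- 0 * params[[nm]]
    if (any(!is.finite(g)))
      stop("non-finite gradient in parameter '", nm, "'")
    m <- beta1 * state$m[[nm]] + (1 - beta1) * g
    v <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    state$m[[nm]] <- m
    state$v[[nm]] <- v
    upd <- lr * (m / bc1) / (sqrt(v / bc2) + eps)
    params[[nm]] <- params[[nm]] - upd - lr * weight_decay * params[[nm]]
  }
  state$t <- t
  list(params = params, state = state)
}

# --- splitting -------------------------------------------------------------

#' Split samples into train and test partitions
#'
#' Random, reproducible, disjoint and exhaustive. Augmentation is never
#' applied here; the training pipeline augments only the training partition
#' so held-out evaluation sees unmodified samples.
#'
#' @param samples a `sample_set` of length >= 2.
#' @param test_fraction fraction held out, in \[0, 1).
#' @param seed integer RNG seed.
#' @param blocked if `TRUE`, hold out whole raster rows instead of random
#'   cells (spatially blocked split).
#' @return list with elements `train` and `test`.
#' @export
split_train_test <- function(samples, test_fraction = 0.30, seed = 1L,
                             blocked = FALSE) {
  n <- length(samples)
  if (n < 2L) stop_input("need at least 2 samples to split")
  if (test_fraction < 0 || test_fraction >= 1)
    stop_input("test_fraction must lie in [0, 1)")
  n_test <- round(n * test_fraction)
  test_idx <- with_seed(seed, {
    if (!blocked) {
      sort(sample.int(n, n_test))
    } else {
      rows <- samples$center %/% samples$dim[2L]
      ur <- sample(unique(rows))
      cum <- cumsum(tabulate(match(rows, ur), length(ur)))
      k <- which.min(abs(cum - n_test))
      which(rows %in% ur[seq_len(k)])
    }
  })
  if (length(test_idx) == 0L)
    return(list(train = samples, test = samples[integer(0)]))
  list(train = samples[-test_idx], test = samples[test_idx])
}

# --- learning-rate range test ---------------------------------------------

# Core sweep shared by the model-level range test and unit tests: one
# optimization step per candidate rate on an exponential grid, recording the
# post-step loss, then smoothing and locating the divergence point.
lr_sweep_core <- function(par, grad_fn, loss_fn, eta_min, eta_max, steps,
                          optimizer = c("adamw", "sgd"), smooth_window = 5L) {
  optimizer <- match.arg(optimizer)
  etas <- exp(seq(log(eta_min), log(eta_max), length.out = steps))
  losses <- numeric(steps)
  state <- NULL
  for (i in seq_len(steps)) {
    g <- grad_fn(par, i)
    if (optimizer == "adamw") {
      st <- adamw_step(par, g, state, lr = etas[i])
      par <- st$params
      state <- st$state
    } else {
      for (nm in names(par)) par[[nm]] <- par[[nm]] - etas[i] * g[[nm]]
    }
    l <- loss_fn(par, i)
    losses[i] <- if (is.finite(l)) l else Inf
    if (!is.finite(l)) {
      losses[i:steps] <- Inf
      break
    }
  }
  k <- min(smooth_window, steps)
  smoothed <- stats::filter(losses, rep(1 / k, k), sides = 1)
  smoothed[seq_len(k - 1L)] <- cumsum(losses[seq_len(k - 1L)]) / seq_len(k - 1L)
  smoothed <- as.numeric(smoothed)
  smoothed[!is.finite(smoothed)] <- Inf
  best <- which.min(smoothed)
  div <- which(smoothed > 4 * smoothed[best] & seq_len(steps) > best)
  diverged <- length(div) > 0L
  suggested <- if (diverged) etas[best] / 10 else etas[steps] / 10
  if (!diverged)
    warning("loss never diverged over the sweep; returning eta_max / 10")
  list(suggested = suggested, etas = etas, losses = losses,
       smoothed = smoothed, diverged = diverged)
}

#' Learning-rate range test
#'
#' Sweeps the learning rate exponentially over `[eta_min, eta_max]` for one
#' pass of mini-batch steps, records the loss per step, and suggests the
#' rate one decade below the divergence point (the minimum of the smoothed
#' loss curve divided by 10).
#'
#' @param model a `rarefynet_model` (a copy is trained; the input is not
#'   modified).
#' @param samples a `sample_set` with reference values.
#' @param eta_min,eta_max sweep bounds.
#' @param steps number of sweep steps (>= 10).
#' @param batch_size mini-batch size.
#' @param seed RNG seed for shuffling and dropout.
#' @return list with `suggested` rate and the per-step `etas`, `losses` and
#'   `smoothed` curve.
#' @export
lr_range_test <- function(model, samples, eta_min = 1e-6, eta_max = 1,
                          steps = 100L, batch_size = 64L, seed = 1L) {
  if (steps < 10L) stop_input("steps must be >= 10")
  n <- length(samples)
  bn <- model$bn
  with_seed(seed, {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    fwd_cache <- new.env(parent = emptyenv())
    grad_fn <- function(par, i) {
      bi <- batches[[((i - 1L) %% length(batches)) + 1L]]
      set <- samples[bi]
      m2 <- model
      m2$params <- par
      m2$bn <- bn
      r <- net_forward(m2, set, training = TRUE)
      bn <<- r$bn
      l <- rmse_loss(r$yhat, set$y)
      fwd_cache$loss <- l
      dy <- if (l > 0) (r$yhat - set$y) / (length(bi) * l) else
        numeric(length(bi))
      net_backward(m2, r$cache, dy)
    }
    loss_fn <- function(par, i) fwd_cache$loss
    sw <- lr_sweep_core(model$params, grad_fn, loss_fn, eta_min, eta_max,
                        steps, optimizer = "adamw")
    if (!is.finite(sw$losses[1L]))
      stop_input("non-finite loss at eta_min")
    sw
  })
}

# --- training loop ---------------------------------------------------------

#' Train a refinement network
#'
#' Mini-batch optimization of the RMSE loss with AdamW at a constant
#' learning rate for a fixed number of epochs (no schedule, no early
#' stopping). The checkpoint with the best test loss is retained alongside
#' the final parameters. Deterministic for a given seed.
#'
#' @param model a `rarefynet_model` (not modified).
#' @param train_set,test_set `sample_set`s with reference values; the test
#'   set may have length 0.
#' @param config a [train_config].
#' @return list with `model` (final), `best` (best-test-loss checkpoint) and
#'   `history` (data.frame epoch/train_loss/test_loss).
#' @export
train_rarefynet <- function(model, train_set, test_set = NULL,
                            config = train_config()) {
  n <- length(train_set)
  if (n == 0L) stop_input("training set is empty")
  if (config$epochs == 0L)
    return(list(model = model, best = model,
                history = data.frame(epoch = integer(0),
                                     train_loss = numeric(0),
                                     test_loss = numeric(0))))
  params <- model$params
  bn <- model$bn
  state <- NULL
  best <- NULL
  best_loss <- Inf
  hist_tr <- numeric(config$epochs)
  hist_te <- rep(NA_real_, config$epochs)
  has_test <- !is.null(test_set) && length(test_set) > 0L
  m2 <- model
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      bl <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        set <- train_set[batches[[bi]]]
        m2$params <- params
        m2$bn <- bn
        r <- net_forward(m2, set, training = TRUE)
        bn <- r$bn
        l <- rmse_loss(r$yhat, set$y)
        if (!is.finite(l)) {
          warning("loss diverged at epoch ", ep, "; returning last checkpoint")
          m2$params <- params; m2$bn <- bn
          hist <- data.frame(epoch = seq_len(ep - 1L),
                             train_loss = hist_tr[seq_len(ep - 1L)],
                             test_loss = hist_te[seq_len(ep - 1L)])
          return(list(model = m2, best = best %||% m2, history = hist))
        }
        bl[bi] <- l
        dy <- if (l > 0) (r$yhat - set$y) / (length(r$yhat) * l) else
          numeric(length(r$yhat))
        grads <- net_backward(m2, r$cache, dy)
        st <- adamw_step(params, grads, state, lr = config$learning_rate,
                         weight_decay = config$weight_decay,
                         beta1 = config$beta1, beta2 = config$beta2,
                         eps = config$eps)
        params <- st$params
        state <- st$state
      }
      hist_tr[ep] <- mean(bl)
      if (has_test) {
        m2$params <- params
        m2$bn <- bn
        te <- net_forward(m2, test_set, training = FALSE,
                          keep_cache = FALSE)$yhat
        hist_te[ep] <- rmse_loss(te, test_set$y)
        if (hist_te[ep] < best_loss) {
          best_loss <- hist_te[ep]
          best <- m2
        }
      }
    }
    m2$params <- params
    m2$bn <- bn
    list(model = m2, best = best %||% m2,
         history = data.frame(epoch = seq_len(config$epochs),
                              train_loss = hist_tr, test_loss = hist_te))
  })
}

# --- hyperparameter search -------------------------------------------------

#' Random-then-grid hyperparameter search
#'
#' Stage 1 draws `budget_random` configurations uniformly from the search
#' space and trains each briefly on a small subset (10% of the samples by
#' default). Stage 2 refines the best draw with a grid over the neighboring
#' candidate values in every dimension. Returns the configuration with the
#' lowest validation loss.
#'
#' @param space named list of candidate value vectors for [train_config]
#'   fields (e.g. `list(learning_rate = c(1e-4, 5e-4, 1e-3))`).
#' @param samples a `sample_set` with reference values.
#' @param budget_random number of random draws in stage 1.
#' @param base_config [train_config] supplying all other fields; its
#'   `epochs` are overridden by `search_epochs`.
#' @param config architecture config used to build the throwaway models.
#' @param subset_fraction fraction of `samples` used for the short fits.
#' @param search_epochs epochs per candidate fit.
#' @param seed RNG seed.
#' @return list with `config` (best [train_config]), and `trace`
#'   (data.frame of evaluated candidates and validation losses).
#' @export
hyperparameter_search <- function(space, samples, budget_random = 8L,
                                  base_config = train_config(),
                                  config = rarefynet_config(),
                                  subset_fraction = 0.10,
                                  search_epochs = 15L, seed = 1L) {
  if (length(space) == 0L || any(lengths(space) == 0L))
    stop_input("empty search space")
  n <- length(samples)
  sub_n <- max(8L, round(n * subset_fraction))
  sub_idx <- with_seed(seed, sample.int(n, min(sub_n, n)))
  sub <- samples[sub_idx]
  parts <- split_train_test(sub, 0.3, seed = seed + 1L)
  eval_candidate <- function(vals, k) {
    cfg <- base_config
    for (nm in names(vals)) cfg[[nm]] <- vals[[nm]]
    cfg$epochs <- as.integer(search_epochs)
    cfg$seed <- seed + 100L + k
    model <- build_model(config, seed = cfg$seed)
    fit <- train_rarefynet(model, parts$train, parts$test, cfg)
    te <- fit$history$test_loss
    min(te[is.finite(te)], Inf)
  }
  draws <- with_seed(seed + 2L, {
    lapply(seq_len(budget_random), function(i)
      lapply(space, function(v) v[sample.int(length(v), 1L)]))
  })
  draws <- unique(draws)
  losses <- vapply(seq_along(draws), function(i)
    eval_candidate(draws[[i]], i), 1)
  best <- draws[[which.min(losses)]]
  # stage 2: grid over the neighbors of the best value in each dimension
  neighbor_vals <- lapply(names(space), function(nm) {
    v <- sort(unique(space[[nm]]))
    i <- which(v == best[[nm]])
    v[max(1L, i - 1L):min(length(v), i + 1L)]
  })
  names(neighbor_vals) <- names(space)
  grid <- expand.grid(neighbor_vals, KEEP.OUT.ATTRS = FALSE)
  gl <- vapply(seq_len(nrow(grid)), function(i)
    eval_candidate(as.list(grid[i, , drop = FALSE]), 1000L + i), 1)
  trace <- rbind(
    data.frame(stage = "random", do.call(rbind.data.frame, draws),
               loss = losses),
  data.frame(stage = "grid", grid, loss = gl))
  winner <- as.list(grid[which.min(gl), , drop = FALSE])
  if (min(losses) < min(gl)) winner <- best
  out <- base_config
  for (nm in names(winner)) out[[nm]] <- winner[[nm]]
  list(config = out, trace = trace)
}
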