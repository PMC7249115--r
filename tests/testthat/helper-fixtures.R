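# Shared fixtures: all built in code, deterministic under explicit seeds.

# a small scene that exercises the full geometry at low cost
tiny_scene_config <- function(seed = 1L, ...) {
  args <- list(size = c(40, 40), gsd = 0.25, cell = 10, vigor_scale = 15,
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(scene_config, args)
}

random_map <- function(nr, nc, seed = 1L, pixel_size = 10) {
  set.seed(seed)
  ndvi_map(matrix(stats::runif(nr * nc, -0.2, 0.9), nr, nc),
           pixel_size = pixel_size)
}

# random training samples with a known target relation y = g(xc)
random_samples <- function(n, seed = 1L, target = function(xc) xc) {
  set.seed(seed)
  set <- list(patch = matrix(stats::runif(n * 9, 0, 1), n, 9),
              loc = matrix(stats::runif(n * 9), n, 9),
              center = seq_len(n) - 1L, npix = n,
              dim = c(1L, n))
  set$xc <- set$patch[, 5]
  set$y <- pmin(1, pmax(0, target(set$xc)))
  class(set) <- "sample_set"
  set
}

# spatially smooth random raster: Gaussian-filtered noise rescaled around
# `center` with the given amplitude, clipped to [0, 1]
make_smooth_map <- function(seed, n = 14, center = 0.5, amp = 0.8) {
  set.seed(seed)
  z <- matrix(stats::rnorm(n * n), n, n)
  k <- exp(-outer(1:n, 1:n, "-")^2 / 8)
  k <- k / rowSums(k)
  z <- k %*% z %*% t(k)
  z <- (z - min(z)) / (max(z) - min(z))
  v <- center + amp * (z - 0.5)
  v[v < 0] <- 0
  v[v > 1] <- 1
  ndvi_map(v)
}

# a model trained on the identity task (reference equals the raw center
# pixel) over patches of smooth rasters spanning several mean levels and
# amplitudes; computed once per test run
identity_fit_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      centers <- c(0.5, 0.2, 0.5, 0.8, 0.35, 0.65)
      amps <- c(0.8, 0.25, 0.25, 0.25, 0.5, 0.5)
      sets <- lapply(1:6, function(s) {
        m <- make_smooth_map(s, center = centers[s], amp = amps[s])
        pair_datasets(m, m)   # y is the center pixel itself
      })
      all <- rarefynet:::rbind_sample_sets(sets)
      parts <- split_train_test(all, 0.25, seed = 1)
      fit <- train_rarefynet(build_model(rarefynet_config(), seed = 1),
                             parts$train, parts$test,
                             train_config(epochs = 150, seed = 1))
      cache <<- list(fit = fit, parts = parts)
    }
    cache
  }
})

# definitional two-pass one-way ANOVA oracle, written independently of the
# implementation: first pass for the means, second for the squared sums
anova_two_pass <- function(groups) {
  all_vals <- unlist(groups)
  gm <- sum(all_vals) / length(all_vals)
  means <- vapply(groups, function(g) sum(g) / length(g), 1)
  ss_c <- 0; ss_e <- 0
  for (j in seq_along(groups)) {
    ss_c <- ss_c + length(groups[[j]]) * (means[j] - gm)^2
    for (v in groups[[j]]) ss_e <- ss_e + (v - means[j])^2
  }
  g <- length(groups); n <- length(all_vals)
  list(df = c(g - 1, n - g), ss = c(ss_c, ss_e),
       ms = c(ss_c / (g - 1), ss_e / (n - g)),
       f = (ss_c / (g - 1)) / (ss_e / (n - g)))
}

# reference Adam (no weight decay), transcribed from the published update
# rule, used as the independent oracle for adamw_step with alpha = 0
adam_reference <- function(theta, grads_seq, lr, beta1 = 0.9, beta2 = 0.999,
                           eps = 1e-8) {
  m <- 0 * theta; v <- 0 * theta
  for (t in seq_along(grads_seq)) {
    g <- grads_seq[[t]]
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    theta <- theta - lr * mhat / (sqrt(vhat) + eps)
  }
  theta
}

# printed one-way ANOVA table of the June validation: raw satellite,
# refined satellite and UAV reference grouped by the surveyed vigor classes
# (three parcels each); columns: ss_classes, ss_error, df_error, F, p
table3_rows <- function() {
  data.frame(
    dataset = rep(c("raw", "refined", "uav"), each = 3),
    parcel = rep(c("A", "B", "C"), 3),
    ss_c = c(0.3084, 0.3938, 0.1985, 0.4749, 1.3735, 0.7071,
             1.3608, 2.7135, 0.9447),
    ss_e = c(1.3821, 2.5353, 1.0228, 0.9189, 1.8812, 0.4515,
             0.7009, 1.2010, 0.8069),
    df_e = c(31, 63, 15, 31, 63, 15, 31, 63, 15),
    f = c(3.4582, 4.8928, 1.4555, 8.0112, 22.9984, 11.7444,
          30.0925, 71.1664, 8.7803),
    p = c(0.044081, 0.010587, 0.264401, 0.001568, 3.17e-8, 0.000852,
          5.46e-8, 6.87e-17, 0.002988))
}
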