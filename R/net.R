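# Residual inception network for NDVI patch refinement.
#
# The network maps a 3x3x2 patch tensor (NDVI neighborhood + location layer)
# to a single refined NDVI value. Two inception blocks of four parallel
# branches (1x1 conv; 1x1 channel-halving then 3x3 conv; 1x1 halving then
# 3x3 conv with dilation 2; 3x3 average pool then 1x1 projection) feed a
# global average pooling layer and a small dense head with dropout. A
# residual connection adds the raw central NDVI pixel to the head output
# before a final single ReLU unit, so the convolutional part only has to
# learn the mixed-pixel correction, not the value itself.
#
# All convolutions act on the fixed 3x3 spatial field with zero padding, so
# they reduce to a gather (im2col) followed by one matrix multiplication;
# a whole mini-batch is processed with a handful of BLAS calls.

#' Architecture configuration
#'
#' @param branches list of 4 branch specs, each a list with `kind` ("conv" or
#'   "pool"), filter size `f` (1 or 3), dilation `k`, and `reduce` (whether a
#'   1x1 convolution halves the incoming channels before the spatial
#'   convolution). The default is the reference layout: 1x1; halve+3x3;
#'   halve+3x3 dilation 2; 3x3 average pool + 1x1 projection.
#' @param maps_block1 feature maps per branch in the first inception block
#'   (default 8; concatenation width 32).
#' @param maps_block2 feature maps per branch in the second block
#'   (default 32; concatenation width 128).
#' @param dense_width hidden units of the first dense layer (default 32).
#' @param dropout dropout probability between the two dense layers
#'   (default 0.2).
#' @param normalize_locations scale the location layer into \[0, 1\]
#'   (default `TRUE`); set `FALSE` to feed raw linear indices.
#' @param bn_momentum,bn_eps batch-normalization running-statistics momentum
#'   and variance floor.
#' @return an object of class `rarefynet_config`.
#' @export
rarefynet_config <- function(branches = default_branches(),
                             maps_block1 = 8L, maps_block2 = 32L,
                             dense_width = 32L, dropout = 0.2,
                             normalize_locations = TRUE,
                             bn_momentum = 0.1, bn_eps = 1e-5) {
  if (length(branches) != 4L)
    stop_input("each inception block has exactly 4 branches")
  for (br in branches) {
    if (!br$kind %in% c("conv", "pool")) stop_input("branch kind must be 'conv' or 'pool'")
    if (!(br$f %in% c(1L, 3L))) stop_input("filter sizes must be 1 or 3 on a 3x3 field")
    if ((br$k %||% 1L) < 1L) stop_input("dilation rate must be >= 1")
  }
  if (dropout < 0 || dropout >= 1) stop_input("dropout must lie in [0, 1)")
  structure(
    list(branches = branches,
         maps_block1 = as.integer(maps_block1),
         maps_block2 = as.integer(maps_block2),
         dense_width = as.integer(dense_width),
         dropout = dropout,
         normalize_locations = isTRUE(normalize_locations),
         bn_momentum = bn_momentum, bn_eps = bn_eps),
    class = "rarefynet_config")
}

default_branches <- function() {
  list(
    list(kind = "conv", f = 1L, k = 1L, reduce = FALSE),
    list(kind = "conv", f = 3L, k = 1L, reduce = TRUE),
    list(kind = "conv", f = 3L, k = 2L, reduce = TRUE),
    list(kind = "pool", f = 3L, k = 1L, reduce = FALSE))
}

# source patch position (1..9, NA = zero pad) for each of the T kernel taps,
# at each of the 9 output positions; taps ordered row-major over offsets
taps_src <- function(f, k) {
  offs <- if (f == 1L) cbind(0L, 0L)
          else cbind(rep(c(-k, 0L, k), each = 3), rep(c(-k, 0L, k), times = 3))
  src <- matrix(NA_integer_, 9L, nrow(offs))
  for (p in 1:9) {
    pr <- (p - 1L) %/% 3L
    pc <- (p - 1L) %% 3L
    for (t in seq_len(nrow(offs))) {
      r2 <- pr + offs[t, 1L]; c2 <- pc + offs[t, 2L]
      if (r2 >= 0L && r2 <= 2L && c2 >= 0L && c2 <= 2L)
        src[p, t] <- r2 * 3L + c2 + 1L
    }
  }
  src
}

glorot <- function(nr, nc) {
  l <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -l, l), nr, nc)
}

#' Build a refinement network with deterministic initialization
#'
#' @param config a [rarefynet_config].
#' @param seed integer; the same seed always yields bit-identical initial
#'   weights.
#' @return an object of class `rarefynet_model` holding the configuration,
#'   the trainable parameters (flat named list) and the batch-normalization
#'   running statistics.
#' @export
build_model <- function(config = rarefynet_config(), seed = 1L) {
  stopifnot(inherits(config, "rarefynet_config"))
  widths <- c(config$maps_block1, config$maps_block2)
  cins <- c(2L, 4L * config$maps_block1)
  layout <- list(blocks = list(), concat2 = 4L * config$maps_block2,
                 tapsets = list())
  params <- list()
  bn <- list()
  with_seed(seed, {
    for (b in 1:2) {
      cin <- cins[b]; cout <- widths[b]
      brs <- list()
      for (j in 1:4) {
        sp <- config$branches[[j]]
        nm <- sprintf("blk%d.br%d", b, j)
        ch <- cin
        if (sp$kind == "conv") {
          if (isTRUE(sp$reduce)) {
            ch <- max(1L, cin %/% 2L)
            params[[paste0(nm, ".rW")]] <- glorot(cin, ch)
            params[[paste0(nm, ".rb")]] <- numeric(ch)
          }
          src <- taps_src(sp$f, sp$k %||% 1L)
          tapkey <- if (sp$f == 1L) NA_character_ else
            sprintf("f%dk%d", sp$f, sp$k %||% 1L)
          params[[paste0(nm, ".W")]] <- glorot(ncol(src) * ch, cout)
          params[[paste0(nm, ".b")]] <- numeric(cout)
        } else {  # pool + 1x1 projection
          src <- taps_src(3L, 1L)
          tapkey <- "f3k1"
          params[[paste0(nm, ".W")]] <- glorot(cin, cout)
          params[[paste0(nm, ".b")]] <- numeric(cout)
        }
        if (!is.na(tapkey)) layout$tapsets[[tapkey]] <- src
        params[[paste0(nm, ".gamma")]] <- rep(1, cout)
        params[[paste0(nm, ".beta")]] <- numeric(cout)
        bn[[nm]] <- list(mean = numeric(cout), var = rep(1, cout))
        brs[[j]] <- list(kind = sp$kind, reduce = isTRUE(sp$reduce) && sp$kind == "conv",
                         ch = ch, cout = cout, src = src, name = nm,
                         tapkey = tapkey)
      }
      layout$blocks[[b]] <- list(cin = cin, branches = brs)
    }
    cw <- layout$concat2
    params[["head.W1"]] <- glorot(cw, config$dense_width)
    params[["head.b1"]] <- numeric(config$dense_width)
    params[["head.W2"]] <- glorot(config$dense_width, 1L)
    params[["head.b2"]] <- numeric(1L)
    # final scalar unit starts at the identity so the untrained model is
    # (approximately) the residual pass-through y = relu(x_center)
    params[["head.w3"]] <- 1
    params[["head.b3"]] <- 0
  })
  structure(list(config = config, layout = layout, params = params, bn = bn,
                 seed = as.integer(seed)),
            class = "rarefynet_model")
}

#' Count trainable parameters
#'
#' Sums weights, biases and batch-normalization scale/shift parameters;
#' batch-norm running statistics are not trainable and are excluded.
#'
#' @param model a `rarefynet_model` (or fitted `rarefynet`).
#' @export
count_parameters <- function(model) {
  if (inherits(model, "rarefynet")) model <- model$model
  sum(vapply(model$params, length, 1L))
}

# --- forward / backward ----------------------------------------------------

# row indices into an (N*9) x C activation matrix that gather patch position
# srcp[p] for every sample; NA marks zero padding
gather_idx <- function(srcp, n) {
  rep(seq.int(0L, by = 9L, length.out = n), each = 9L) + rep(srcp, times = n)
}

gather_rows <- function(X, idx) {
  out <- X[idx, , drop = FALSE]
  bad <- is.na(idx)
  if (any(bad)) out[bad, ] <- 0
  out
}

col_mul <- function(M, s) M * rep(s, rep.int(nrow(M), length(s)))

bn_forward <- function(Z, gamma, beta, state, eps, momentum, training) {
  M <- nrow(Z)
  if (training) {
    mu <- colMeans(Z)
    Zc <- add_bias(Z, -mu)
    v <- colSums(Zc * Zc) / M
    istd <- 1 / sqrt(v + eps)
    xhat <- col_mul(Zc, istd)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v * M / max(M - 1, 1)
  } else {
    istd <- 1 / sqrt(state$var + eps)
    xhat <- col_mul(add_bias(Z, -state$mean), istd)
  }
  list(out = add_bias(col_mul(xhat, gamma), beta),
       xhat = xhat, istd = istd, state = state)
}

bn_backward <- function(dY, gamma, xhat, istd) {
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- col_mul(dY, gamma)
  # dZ = istd * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat))
  dZ <- col_mul(add_bias(dxhat, -colMeans(dxhat)), istd) -
    col_mul(xhat, istd * colMeans(dxhat * xhat))
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

branch_forward <- function(br, params, bn, X, n, eps, momentum, training,
                           idx) {
  cache <- list()
  Zin <- X
  if (br$reduce) {
    Zin <- add_bias(X %*% params[[paste0(br$name, ".rW")]],
                    params[[paste0(br$name, ".rb")]])
    cache$Zin <- Zin
  }
  if (br$kind == "conv") {
    # a 1x1 convolution reads each position in place: no gather needed
    Xc <- if (is.null(idx)) Zin else
      do.call(cbind, lapply(idx, function(i) gather_rows(Zin, i)))
    Z <- add_bias(Xc %*% params[[paste0(br$name, ".W")]],
                  params[[paste0(br$name, ".b")]])
    cache$Xc <- Xc; cache$idx <- idx
  } else {
    pooled <- Reduce(`+`, lapply(idx, function(i) gather_rows(Zin, i))) /
      length(idx)
    Z <- add_bias(pooled %*% params[[paste0(br$name, ".W")]],
                  params[[paste0(br$name, ".b")]])
    cache$pooled <- pooled; cache$idx <- idx
  }
  bnr <- bn_forward(Z, params[[paste0(br$name, ".gamma")]],
                    params[[paste0(br$name, ".beta")]],
                    bn[[br$name]], eps, momentum, training)
  A <- elu(bnr$out)
  cache$Zbn <- bnr$out; cache$xhat <- bnr$xhat; cache$istd <- bnr$istd
  cache$A <- A
  list(out = A, cache = cache, bn_state = bnr$state)
}

branch_backward <- function(br, params, cache, dA, X, n, need_dX) {
  grads <- list()
  dZbn <- elu_backward(dA, cache$Zbn, cache$A)
  bb <- bn_backward(dZbn, params[[paste0(br$name, ".gamma")]],
                    cache$xhat, cache$istd)
  grads[[paste0(br$name, ".gamma")]] <- bb$dgamma
  grads[[paste0(br$name, ".beta")]] <- bb$dbeta
  dZ <- bb$dZ
  if (br$kind == "conv") {
    W <- params[[paste0(br$name, ".W")]]
    grads[[paste0(br$name, ".W")]] <- crossprod(cache$Xc, dZ)
    grads[[paste0(br$name, ".b")]] <- colSums(dZ)
    dXc <- dZ %*% t(W)
    if (is.null(cache$idx)) {  # 1x1 conv: in-place read, in-place scatter
      dZin <- dXc
    } else {
      ch <- br$ch
      dZin <- matrix(0, nrow(dZ), ch)
      for (t in seq_along(cache$idx)) {
        block <- dXc[, ((t - 1L) * ch + 1L):(t * ch), drop = FALSE]
        idx <- cache$idx[[t]]
        ok <- !is.na(idx)
        dZin[idx[ok], ] <- dZin[idx[ok], ] + block[ok, , drop = FALSE]
      }
    }
  } else {
    W <- params[[paste0(br$name, ".W")]]
    grads[[paste0(br$name, ".W")]] <- crossprod(cache$pooled, dZ)
    grads[[paste0(br$name, ".b")]] <- colSums(dZ)
    dpooled <- dZ %*% t(W) / length(cache$idx)
    dZin <- matrix(0, nrow(dZ), ncol(dpooled))
    for (idx in cache$idx) {
      ok <- !is.na(idx)
      dZin[idx[ok], ] <- dZin[idx[ok], ] + dpooled[ok, , drop = FALSE]
    }
  }
  if (br$reduce) {
    rW <- params[[paste0(br$name, ".rW")]]
    grads[[paste0(br$name, ".rW")]] <- crossprod(X, dZin)
    grads[[paste0(br$name, ".rb")]] <- colSums(dZin)
    dX <- if (need_dX) dZin %*% t(rW) else NULL
  } else {
    dX <- if (need_dX) dZin else NULL
  }
  list(grads = grads, dX = dX)
}

# Forward pass over a batch. `set` is a sample_set (or compatible list with
# patch/loc/xc). Returns yhat plus (optionally) the cache for backprop and
# updated batch-norm running statistics.
net_forward <- function(model, set, training = FALSE, keep_cache = training) {
  n <- nrow(set$patch)
  X <- cbind(as.vector(t(set$patch)), as.vector(t(set$loc)))
  cfg <- model$config
  params <- model$params
  bn <- model$bn
  cache <- list(n = n, X = X, xc = set$xc)
  idxsets <- lapply(model$layout$tapsets, function(src)
    lapply(seq_len(ncol(src)), function(t) gather_idx(src[, t], n)))
  acts <- X
  for (b in 1:2) {
    blk <- model$layout$blocks[[b]]
    outs <- vector("list", 4L)
    bcaches <- vector("list", 4L)
    for (j in 1:4) {
      br <- blk$branches[[j]]
      r <- branch_forward(br, params, bn, acts, n, cfg$bn_eps,
                          cfg$bn_momentum, training,
                          if (is.na(br$tapkey)) NULL else idxsets[[br$tapkey]])
      outs[[j]] <- r$out
      bcaches[[j]] <- r$cache
      bn[[br$name]] <- r$bn_state
    }
    if (keep_cache) {
      cache[[paste0("blk", b, "_in")]] <- acts
      cache[[paste0("blk", b)]] <- bcaches
    }
    acts <- do.call(cbind, outs)
  }
  # global average pooling over the 9 patch positions
  C <- ncol(acts)
  G <- colMeans(array(acts, dim = c(9L, n, C)), dims = 1L)
  if (n == 1L) G <- matrix(G, 1L)
  H1pre <- add_bias(G %*% params$head.W1, params$head.b1)
  H1 <- elu(H1pre)
  if (training && cfg$dropout > 0) {
    mask <- (matrix(stats::runif(length(H1)), nrow(H1)) >= cfg$dropout) /
      (1 - cfg$dropout)
    D <- H1 * mask
  } else {
    mask <- NULL
    D <- H1
  }
  H2pre <- add_bias(D %*% params$head.W2, params$head.b2)
  Z2 <- elu(H2pre)
  S <- Z2[, 1L] + set$xc          # residual: add the raw central NDVI pixel
  Opre <- S * params$head.w3 + params$head.b3
  yhat <- relu(Opre)
  if (keep_cache) {
    cache$G <- G; cache$H1pre <- H1pre; cache$H1 <- H1; cache$mask <- mask
    cache$D <- D; cache$H2pre <- H2pre; cache$Z2 <- Z2; cache$S <- S
    cache$Opre <- Opre
  }
  list(yhat = yhat, cache = if (keep_cache) cache else NULL, bn = bn)
}

net_backward <- function(model, cache, dyhat) {
  params <- model$params
  n <- cache$n
  grads <- list()
  dOpre <- dyhat * (cache$Opre > 0)
  grads$head.w3 <- sum(dOpre * cache$S)
  grads$head.b3 <- sum(dOpre)
  dS <- dOpre * params$head.w3
  dH2pre <- elu_backward(matrix(dS, n, 1L), cache$H2pre, cache$Z2)
  grads$head.W2 <- crossprod(cache$D, dH2pre)
  grads$head.b2 <- colSums(dH2pre)
  dD <- dH2pre %*% t(params$head.W2)
  dH1 <- if (is.null(cache$mask)) dD else dD * cache$mask
  dH1pre <- elu_backward(dH1, cache$H1pre, cache$H1)
  grads$head.W1 <- crossprod(cache$G, dH1pre)
  grads$head.b1 <- colSums(dH1pre)
  dG <- dH1pre %*% t(params$head.W1)
  dA <- dG[rep(seq_len(n), each = 9L), , drop = FALSE] / 9
  for (b in 2:1) {
    blk <- model$layout$blocks[[b]]
    bin <- cache[[paste0("blk", b, "_in")]]
    bcaches <- cache[[paste0("blk", b)]]
    need_dX <- b > 1L
    dXacc <- if (need_dX) matrix(0, nrow(bin), ncol(bin)) else NULL
    col0 <- 0L
    for (j in 1:4) {
      br <- blk$branches[[j]]
      cols <- (col0 + 1L):(col0 + br$cout)
      col0 <- col0 + br$cout
      r <- branch_backward(br, params, bcaches[[j]],
                           dA[, cols, drop = FALSE], bin, n, need_dX)
      grads[names(r$grads)] <- r$grads
      if (need_dX) dXacc <- dXacc + r$dX
    }
    if (need_dX) dA <- dXacc
  }
  grads
}

#' Evaluate the network on patch tensors
#'
#' Inference-mode forward pass (batch-normalization uses running statistics,
#' dropout is off). A batch evaluation equals the per-sample evaluations.
#'
#' @param object a `rarefynet_model`.
#' @param newdata a `sample_set`, or a single `patch_tensor`.
#' @param ... unused.
#' @return numeric vector of refined NDVI values (all `>= 0` by the final
#'   ReLU unit).
#' @export
predict.rarefynet_model <- function(object, newdata, ...) {
  set <- as_flat_batch(newdata)
  net_forward(object, set, training = FALSE, keep_cache = FALSE)$yhat
}

as_flat_batch <- function(x) {
  if (inherits(x, "sample_set")) return(x)
  if (inherits(x, "patch_tensor")) {
    p <- as.vector(t(x$patch))
    l <- as.vector(t(x$locations))
    return(list(patch = matrix(p, 1L, 9L), loc = matrix(l, 1L, 9L),
                xc = p[5L]))
  }
  stop_input("newdata must be a sample_set or patch_tensor")
}

#' @export
print.rarefynet_model <- function(x, ...) {
  cat(sprintf(
    "<rarefynet_model> 2 inception blocks (4 branches, %d+%d maps/branch), dense %d, dropout %.2g\n",
    x$config$maps_block1, x$config$maps_block2, x$config$dense_width,
    x$config$dropout))
  cat(sprintf("  %d trainable parameters\n", count_parameters(x)))
  invisible(x)
}
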