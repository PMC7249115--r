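# Internal helpers shared across the package.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never clobber the
# user's stream.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Add a per-column bias vector b to matrix M without an explicit sweep().
add_bias <- function(M, b) {
  M + rep(b, rep.int(nrow(M), length(b)))
}

elu <- function(x) {
  neg <- which(x < 0)
  if (length(neg)) x[neg] <- expm1(x[neg])
  x
}

# derivative of ELU given pre-activation x and activation y = elu(x):
# 1 for x > 0, exp(x) = y + 1 otherwise
elu_grad <- function(x, y) {
  g <- rep.int(1, length(x))
  neg <- which(x < 0)
  g[neg] <- y[neg] + 1
  dim(g) <- dim(x)
  g
}

# backprop through ELU: dL/dx given upstream dL/dy, pre-activation x and
# activation y, without materializing the full gradient matrix
elu_backward <- function(dY, x, y) {
  neg <- which(x < 0)
  if (length(neg)) dY[neg] <- dY[neg] * (y[neg] + 1)
  dY
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Sum over f x f non-overlapping blocks of a matrix. nrow and ncol must be
# multiples of f. Returns a (nrow/f) x (ncol/f) matrix.
block_sum <- function(v, f) {
  nr <- nrow(v)
  nc <- ncol(v)
  stopifnot(nr %% f == 0, nc %% f == 0)
  # collapse row-blocks (column-major fill groups f consecutive rows)
  a <- matrix(colSums(matrix(v, nrow = f)), nrow = nr %/% f)   # (nr/f) x nc
  t(matrix(colSums(matrix(t(a), nrow = f)), nrow = nc %/% f))  # (nr/f) x (nc/f)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("rarefynet_input_error", "error")))
}
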