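# Internal dense-network machinery: layers, forward/backward passes and Adam.
#
# Everything operates on samples-in-rows matrices. An "mlp" is an ordered list
# of blocks; each block is dense -> (optional batch norm) -> activation.
# Batch normalization follows the usual convention: batch statistics in
# training mode, exponentially averaged running statistics in eval mode
# (momentum 0.1, eps 1e-5), placed after the dense layer and before the
# activation, with affine scale/shift parameters.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# He (fan-in) initialization, appropriate for rectifier activations. Assumes
# the caller has seeded the RNG.
init_dense <- function(d_in, d_out) {
  list(W = matrix(stats::rnorm(d_in * d_out, sd = sqrt(2 / d_in)), d_in, d_out),
       b = numeric(d_out))
}

init_block <- function(d_in, d_out, batchnorm, activation) {
  block <- init_dense(d_in, d_out)
  block$batchnorm <- isTRUE(batchnorm)
  block$activation <- activation  # "relu", "linear" or "sigmoid"
  if (block$batchnorm) {
    block$gamma <- rep(1, d_out)
    block$beta <- numeric(d_out)
    block$run_mean <- numeric(d_out)
    block$run_var <- rep(1, d_out)
  }
  block
}

# widths: vector of hidden widths, input dim first element excluded.
# batchnorm applies to all blocks; final_activation overrides the last block.
init_mlp <- function(d_in, widths, batchnorm = TRUE, activation = "relu",
                     final_activation = activation) {
  dims <- c(d_in, widths)
  blocks <- vector("list", length(widths))
  for (l in seq_along(widths)) {
    act <- if (l == length(widths)) final_activation else activation
    blocks[[l]] <- init_block(dims[l], dims[l + 1L], batchnorm, act)
  }
  structure(list(blocks = blocks, d_in = d_in, widths = widths), class = "mlp")
}

activate <- function(u, kind) {
  switch(kind,
         relu = (u > 0) * u,
         linear = u,
         sigmoid = 1 / (1 + exp(-u)),
         stopf("unknown activation '%s'", kind))
}

# Forward through one block; returns output plus the cache needed by backward.
# `training` selects batch vs running statistics for batch norm; running stats
# are updated in place on the returned block.
block_forward <- function(block, X, training) {
  U <- X %*% block$W
  U <- sweep(U, 2L, block$b, "+")
  cache <- list(X = X)
  if (block$batchnorm) {
    if (training) {
      n <- nrow(U)
      mu <- colMeans(U)
      v <- colMeans(sweep(U, 2L, mu)^2)  # biased (batch) variance
      unbias <- if (n > 1L) n / (n - 1L) else 1
      block$run_mean <- (1 - BN_MOMENTUM) * block$run_mean + BN_MOMENTUM * mu
      block$run_var <- (1 - BN_MOMENTUM) * block$run_var + BN_MOMENTUM * v * unbias
    } else {
      mu <- block$run_mean
      v <- block$run_var
    }
    inv_sd <- 1 / sqrt(v + BN_EPS)
    Xhat <- sweep(sweep(U, 2L, mu), 2L, inv_sd, "*")
    U2 <- sweep(sweep(Xhat, 2L, block$gamma, "*"), 2L, block$beta, "+")
    cache$Xhat <- Xhat
    cache$inv_sd <- inv_sd
    cache$training <- training
  } else {
    U2 <- U
  }
  cache$pre_act <- U2
  out <- activate(U2, block$activation)
  if (block$activation == "sigmoid") cache$out <- out
  list(out = out, cache = cache, block = block)
}

# Backward through one block given dOut (gradient wrt block output).
# Returns gradients for the block parameters and dX.
block_backward <- function(block, cache, dOut) {
  dU2 <- switch(block$activation,
                relu = dOut * (cache$pre_act > 0),
                linear = dOut,
                sigmoid = dOut * cache$out * (1 - cache$out))
  grads <- list()
  if (block$batchnorm) {
    n <- nrow(dU2)
    grads$gamma <- colSums(dU2 * cache$Xhat)
    grads$beta <- colSums(dU2)
    dXhat <- sweep(dU2, 2L, block$gamma, "*")
    if (isTRUE(cache$training)) {
      # standard batch-norm backward through the batch statistics
      s1 <- colSums(dXhat)
      s2 <- colSums(dXhat * cache$Xhat)
      dU <- sweep(dXhat, 2L, s1 / n) - sweep(cache$Xhat, 2L, s2 / n, "*")
      dU <- sweep(dU, 2L, cache$inv_sd, "*")
    } else {
      dU <- sweep(dXhat, 2L, cache$inv_sd, "*")
    }
  } else {
    dU <- dU2
  }
  grads$W <- crossprod(cache$X, dU)
  grads$b <- colSums(dU)
  list(grads = grads, dX = dU %*% t(block$W))
}

mlp_forward <- function(mlp, X, training = FALSE) {
  caches <- vector("list", length(mlp$blocks))
  out <- X
  for (l in seq_along(mlp$blocks)) {
    step <- block_forward(mlp$blocks[[l]], out, training)
    mlp$blocks[[l]] <- step$block  # running stats may have been updated
    caches[[l]] <- step$cache
    out <- step$out
  }
  list(out = out, caches = caches, mlp = mlp)
}

mlp_backward <- function(mlp, caches, dOut) {
  grads <- vector("list", length(mlp$blocks))
  for (l in rev(seq_along(mlp$blocks))) {
    step <- block_backward(mlp$blocks[[l]], caches[[l]], dOut)
    grads[[l]] <- step$grads
    dOut <- step$dX
  }
  list(grads = grads, dX = dOut)
}

mlp_param_count <- function(mlp, include_batchnorm = TRUE) {
  total <- 0L
  for (b in mlp$blocks) {
    total <- total + length(b$W) + length(b$b)
    if (include_batchnorm && b$batchnorm) {
      total <- total + length(b$gamma) + length(b$beta)
    }
  }
  total
}

# ---- Adam ------------------------------------------------------------------
# Parameters live in nested lists (mlp$blocks[[l]]$W, ...). The optimizer
# walks the model and gradient structures in parallel.

adam_state_new <- function() new.env(parent = emptyenv())

adam_update_array <- function(state, key, param, grad, lr, t,
                              beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(state[[key]])) {
    state[[key]] <- list(m = param * 0, v = param * 0)
  }
  s <- state[[key]]
  s$m <- beta1 * s$m + (1 - beta1) * grad
  s$v <- beta2 * s$v + (1 - beta2) * grad^2
  state[[key]] <- s
  mhat <- s$m / (1 - beta1^t)
  vhat <- s$v / (1 - beta2^t)
  param - lr * mhat / (sqrt(vhat) + eps)
}

adam_update_mlp <- function(state, prefix, mlp, grads, lr, t) {
  for (l in seq_along(mlp$blocks)) {
    g <- grads[[l]]
    for (p in names(g)) {
      key <- paste(prefix, l, p, sep = ".")
      mlp$blocks[[l]][[p]] <- adam_update_array(
        state, key, mlp$blocks[[l]][[p]], g[[p]], lr, t)
    }
  }
  mlp
}
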