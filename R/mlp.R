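# Minimal dense feed-forward network on base matrix ops (BLAS-backed
# matmuls, fused C++ kernels for bias/ReLU/Adam). Layers are lists of
# (W, b); ReLU on all layers except the last (linear). Used for the
# contrastive encoder, its projection head, and the classification head.
#
# Ownership convention: the C++ kernels mutate in place, so layer matrices
# are only ever updated on objects the training loop owns exclusively
# (freshly initialized or deep-copied via copy_layers()).

nn_init <- function(dims, seed = NULL) {
  build <- function() {
    layers <- vector("list", length(dims) - 1L)
    for (i in seq_along(layers)) {
      fan_in <- dims[i]
      layers[[i]] <- list(
        W = matrix(rnorm(dims[i] * dims[i + 1L], sd = sqrt(2 / fan_in)),
                   dims[i], dims[i + 1L]),
        b = numeric(dims[i + 1L])
      )
    }
    attr(layers, "dims") <- dims
    layers
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

copy_layers <- function(layers) {
  out <- lapply(layers, function(l) list(W = l$W + 0, b = l$b + 0))
  attr(out, "dims") <- attr(layers, "dims")
  out
}

# forward pass; with keep_cache = TRUE returns layer inputs for backprop
nn_forward <- function(layers, X, keep_cache = FALSE) {
  n_l <- length(layers)
  cache <- if (keep_cache) vector("list", n_l + 1L)
  A <- X
  for (i in seq_len(n_l)) {
    if (keep_cache) cache[[i]] <- A
    Z <- A %*% layers[[i]]$W        # fresh matrix: in-place kernels are safe
    add_bias_inplace(Z, layers[[i]]$b)
    if (i < n_l) relu_inplace(Z)
    A <- Z
  }
  if (keep_cache) { cache[[n_l + 1L]] <- A; list(out = A, cache = cache) }
  else A
}

# backprop given dOut = dLoss/dOutput; returns per-layer grads and dX
nn_backward <- function(layers, cache, dOut) {
  n_l <- length(layers)
  grads <- vector("list", n_l)
  dZ <- dOut
  for (i in n_l:1) {
    A_in <- cache[[i]]
    if (i < n_l) relu_backward_inplace(dZ, cache[[i + 1L]])
    grads[[i]] <- list(W = crossprod(A_in, dZ), b = colSums(dZ))
    dZ <- tcrossprod(dZ, layers[[i]]$W)   # becomes next dOut (fresh matrix)
  }
  list(grads = grads, dX = dZ)
}

add_grads <- function(g1, g2) {
  Map(function(a, b) list(W = a$W + b$W, b = a$b + b$b), g1, g2)
}

adam_init <- function(layers) {
  lapply(layers, function(l) list(
    mW = matrix(0, nrow(l$W), ncol(l$W)), vW = matrix(0, nrow(l$W), ncol(l$W)),
    mb = numeric(length(l$b)), vb = numeric(length(l$b))
  ))
}

# in-place Adam step on layers the caller owns exclusively
adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  lr_t <- lr * sqrt(1 - beta2^t) / (1 - beta1^t)
  for (i in seq_along(layers)) {
    adam_update_inplace(layers[[i]]$W, state[[i]]$mW, state[[i]]$vW,
                        grads[[i]]$W, lr_t, beta1, beta2, eps)
    adam_update_inplace(layers[[i]]$b, state[[i]]$mb, state[[i]]$vb,
                        grads[[i]]$b, lr_t, beta1, beta2, eps)
  }
  invisible(NULL)
}

# row-wise L2 normalization; guard = TRUE errors on zero rows (cosine
# undefined), guard = FALSE leaves zero rows as zeros
l2_normalize_rows <- function(Z, guard = TRUE) {
  nrm <- sqrt(rowSums(Z^2))
  if (any(nrm == 0)) {
    if (guard) stop_invalid("zero-norm embedding: cosine undefined")
    nrm[nrm == 0] <- 1
  }
  list(U = Z / nrm, norm = nrm)
}
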