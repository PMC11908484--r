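#' Encoder architecture specification
#'
#' Fully connected encoder with ReLU hidden activations and a linear
#' 10-dimensional bottleneck, layer widths `[63, 500, 500, 2000, 10]`.
#' During contrastive pretraining a projection head (two dense layers ending
#' at width 10) sits on top of the bottleneck; the contrastive loss operates
#' on projection outputs while pseudolabeling uses the bottleneck embeddings.
#'
#' @param layer_dims encoder widths, input first (default
#'   `c(63, 500, 500, 2000, 10)`).
#' @param projection_width width of the projection head output (default 10).
#' @return object of class `encoder_spec`.
#' @export
encoder_spec <- function(layer_dims = c(63, 500, 500, 2000, 10),
                         projection_width = 10) {
  if (length(layer_dims) < 2) stop_invalid("need at least input and output dims")
  structure(list(layer_dims = as.integer(layer_dims),
                 projection_width = as.integer(projection_width)),
            class = "encoder_spec")
}

#' Contrastive pretraining configuration
#'
#' @param temperature softmax temperature tau of the contrastive loss
#'   (default 0.1).
#' @param max_rel_noise maximum relative augmentation noise level
#'   (default 0.075): each row's additive Gaussian noise has standard
#'   deviation `u * max_rel_noise * range(row)` with `u ~ Uniform(0, 1)`.
#' @param epochs training epochs (default 25).
#' @param batch_size minibatch size (default 256).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param queue_size nearest-neighbor memory queue capacity (default 8192,
#'   clipped to the dataset size).
#' @param seed integer seed.
#' @return object of class `contrastive_config`.
#' @export
contrastive_config <- function(temperature = 0.1, max_rel_noise = 0.075,
                               epochs = 25, batch_size = 256,
                               learning_rate = 1e-3, queue_size = 8192,
                               seed = 1L) {
  if (temperature <= 0) stop_invalid("temperature must be > 0")
  if (max_rel_noise < 0 || max_rel_noise >= 1)
    stop_invalid("max_rel_noise must be in [0, 1)")
  structure(list(temperature = temperature, max_rel_noise = max_rel_noise,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 queue_size = as.integer(queue_size), seed = as.integer(seed)),
            class = "contrastive_config")
}

#' Gaussian feature augmentation
#'
#' Adds row-wise Gaussian noise: for each row a level `u ~ Uniform(0, 1)` is
#' drawn and the noise standard deviation is `u * max_rel_noise * scale(row)`
#' where `scale(row)` is the row's peak-to-peak range, keeping the
#' perturbation commensurate across spikes of different size.
#'
#' @param features n x d numeric matrix.
#' @param max_rel_noise maximum relative noise level (0 disables).
#' @param seed optional seed (the training loops pass `NULL` and consume the
#'   ambient RNG stream).
#' @return matrix of the same shape.
#' @export
augment <- function(features, max_rel_noise = 0.075, seed = NULL) {
  run <- function() {
    if (max_rel_noise == 0 || nrow(features) == 0) return(features)
    n <- nrow(features); d <- ncol(features)
    scale <- apply(features, 1, max) - apply(features, 1, min)
    sds <- runif(n) * max_rel_noise * scale
    features + matrix(rnorm(n * d), n, d) * sds
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Contrastive (NNCLR-style) loss for one anchor
#'
#' Evaluates `-log( exp(sim(z, z_pos)/tau) / sum_j exp(sim(z, z_j)/tau) )`
#' where `sim` is cosine similarity and the sum runs over the full support
#' set (the designated positive plus all other entries). Nonnegative; zero
#' exactly when the support set contains only the positive.
#'
#' @param anchor numeric embedding vector (nonzero).
#' @param support matrix whose rows are the support embeddings, including the
#'   positive (all nonzero).
#' @param positive row index of the positive in `support` (default 1).
#' @param temperature tau (default 0.1).
#' @return scalar loss.
#' @export
nnclr_loss <- function(anchor, support, positive = 1L, temperature = 0.1) {
  support <- as.matrix(support)
  if (sqrt(sum(anchor^2)) == 0) stop_invalid("zero-norm anchor embedding")
  nrm <- sqrt(rowSums(support^2))
  if (any(nrm == 0)) stop_invalid("zero-norm support embedding")
  u <- anchor / sqrt(sum(anchor^2))
  sims <- as.numeric((support / nrm) %*% u) / temperature
  m <- max(sims)
  lse <- m + log(sum(exp(sims - m)))
  lse - sims[positive]
}

# FIFO push of `rows` into the circular memory queue at write pointer `ptr`
# (0-based); oldest entries are overwritten first
queue_push <- function(queue, ptr, rows) {
  q_size <- nrow(queue)
  k <- min(nrow(rows), q_size)
  slots <- ((ptr + seq_len(k) - 1L) %% q_size) + 1L
  queue[slots, ] <- rows[seq_len(k), , drop = FALSE]
  list(queue = queue, ptr = (ptr + k) %% q_size)
}

#' Contrastive pretraining of the spike encoder
#'
#' Trains the encoder self-supervised, NNCLR-style: every minibatch is
#' augmented twice; the first view's projection selects, for each anchor, its
#' nearest (cosine) neighbor in a FIFO memory queue of past embeddings, which
#' serves as the positive for the second view. The loss is the InfoNCE
#' softmax of each positive against the batch's second-view embeddings (the
#' batch is the contrast set, so inter-sample repulsion keeps the
#' representation from collapsing); gradients flow through the second view's
#' path (encoder + projection head), the queue lookup is a stop-gradient.
#' The queue is refreshed with the second view's embeddings after every
#' step. Optimized with Adam.
#'
#' @param features n x d feature matrix (d must equal `spec$layer_dims[1]`).
#' @param spec an [encoder_spec()].
#' @param cfg a [contrastive_config()].
#' @return object of class `spike_encoder`: encoder layers, projection head,
#'   `spec`, `cfg`, per-epoch mean loss in `epoch_loss`, and a weight
#'   `fingerprint`. With `cfg$epochs = 0` the randomly initialized encoder is
#'   returned (usable by [embed_all()]).
#' @export
pretrain <- function(features, spec = encoder_spec(), cfg = contrastive_config()) {
  features <- as.matrix(features)
  if (ncol(features) != spec$layer_dims[1])
    stop_invalid("feature width ", ncol(features), " != encoder input dim ",
                 spec$layer_dims[1])
  n <- nrow(features)
  # global input conditioning: gradient features carry a 1/dt factor (units
  # 1/s), so bring the mean absolute value to 1; one dataset-level constant,
  # stored with the model and applied by every consumer
  input_scale <- {
    ma <- mean(abs(features))
    if (is.finite(ma) && ma > 0) 1 / ma else 1
  }
  features <- features * input_scale
  with_seed(cfg$seed, {
    enc <- nn_init(spec$layer_dims)
    bott <- spec$layer_dims[length(spec$layer_dims)]
    proj <- nn_init(c(bott, spec$projection_width, spec$projection_width))
    epoch_loss <- numeric(0)
    if (cfg$epochs > 0) {
      if (n < 2) stop_invalid("need at least 2 samples to pretrain")
      bs <- min(cfg$batch_size, n)
      q_size <- max(2L, min(cfg$queue_size, n))
      # seed the queue with embeddings of a random augmented subset
      q_idx <- sample.int(n, q_size)
      q_emb <- nn_forward(proj, nn_forward(enc,
        augment(features[q_idx, , drop = FALSE], cfg$max_rel_noise)))
      queue <- l2_normalize_rows(q_emb, guard = FALSE)$U
      q_ptr <- 0L
      st_enc <- adam_init(enc); st_proj <- adam_init(proj)
      t_step <- 0L
      tau <- cfg$temperature
      for (ep in seq_len(cfg$epochs)) {
        ord <- sample.int(n)
        losses <- numeric(0)
        for (start in seq(1L, n, by = bs)) {
          b <- ord[start:min(start + bs - 1L, n)]
          if (length(b) < 2L) next
          X <- features[b, , drop = FALSE]
          m_b <- length(b)
          A1 <- augment(X, cfg$max_rel_noise)
          A2 <- augment(X, cfg$max_rel_noise)
          f1 <- nn_forward(enc, A1, keep_cache = TRUE)
          p1 <- nn_forward(proj, f1$out, keep_cache = TRUE)
          f2 <- nn_forward(enc, A2, keep_cache = TRUE)
          p2 <- nn_forward(proj, f2$out, keep_cache = TRUE)
          nz1 <- l2_normalize_rows(p1$out, guard = FALSE)
          nz2 <- l2_normalize_rows(p2$out, guard = FALSE)
          # positives: nearest queue entry to each view (stop-gradient).
          # InfoNCE over the batch, symmetrized across views: for term A the
          # anchor NN(z1_i) is contrasted against all view-2 embeddings
          # (M[i, j] = sim(NN(z1_i), z2_j) / tau, positive on the diagonal),
          # term B swaps the views. The batch contrast set keeps inter-sample
          # repulsion in the gradient, preventing representational collapse.
          contrast <- function(zan, zgn) {
            P <- queue[max.col(zan %*% t(queue), ties.method = "first"), ,
                       drop = FALSE]
            M <- (P %*% t(zgn)) / tau
            mx <- apply(M, 1, max)
            lse <- mx + log(rowSums(exp(M - mx)))
            S <- exp(M - lse)
            # dL/dzgn_j = sum_i (S_ij - delta_ij) P_i / (tau * m)
            list(loss = mean(lse - diag(M)),
                 dzgn = crossprod(S - diag(m_b), P) / (tau * m_b))
          }
          cA <- contrast(nz1$U, nz2$U)
          cB <- contrast(nz2$U, nz1$U)
          losses <- c(losses, (cA$loss + cB$loss) / 2)
          # through the L2 normalization, half weight per direction
          dz2 <- 0.5 * (cA$dzgn - rowSums(cA$dzgn * nz2$U) * nz2$U) / nz2$norm
          dz1 <- 0.5 * (cB$dzgn - rowSums(cB$dzgn * nz1$U) * nz1$U) / nz1$norm
          bp2 <- nn_backward(proj, p2$cache, dz2)
          be2 <- nn_backward(enc, f2$cache, bp2$dX)
          bp1 <- nn_backward(proj, p1$cache, dz1)
          be1 <- nn_backward(enc, f1$cache, bp1$dX)
          g_proj <- add_grads(bp1$grads, bp2$grads)
          g_enc <- add_grads(be1$grads, be2$grads)
          t_step <- t_step + 1L
          adam_step(proj, g_proj, st_proj, cfg$learning_rate, t_step)
          adam_step(enc, g_enc, st_enc, cfg$learning_rate, t_step)
          z2n <- nz2$U
          # FIFO queue refresh
          qu <- queue_push(queue, q_ptr, z2n)
          queue <- qu$queue; q_ptr <- qu$ptr
        }
        epoch_loss <- c(epoch_loss, mean(losses))
      }
    }
    structure(list(layers = enc, proj_layers = proj, spec = spec, cfg = cfg,
                   input_scale = input_scale, epoch_loss = epoch_loss,
                   fingerprint = param_fingerprint(enc)),
              class = "spike_encoder")
  })
}

#' @export
print.spike_encoder <- function(x, ...) {
  cat(sprintf("<spike_encoder> dims [%s], %d epochs trained\n",
              paste(x$spec$layer_dims, collapse = ", "),
              length(x$epoch_loss)))
  if (length(x$epoch_loss))
    cat(sprintf("  loss %.4f -> %.4f\n", x$epoch_loss[1],
                x$epoch_loss[length(x$epoch_loss)]))
  invisible(x)
}

#' Embed waveform features into the latent space
#'
#' Deterministic forward pass through the (pretrained or fine-tuned) encoder
#' bottleneck; no projection head, no augmentation.
#'
#' @param encoder a [pretrain()] result (`spike_encoder`) or a
#'   `spike_classifier` (its encoder part is used).
#' @param features n x d feature matrix.
#' @return n x 10 latent matrix.
#' @export
embed_all <- function(encoder, features) {
  layers <- if (inherits(encoder, "spike_classifier")) encoder$enc_layers
            else encoder$layers
  features <- as.matrix(features) * (encoder$input_scale %||% 1)
  if (nrow(features) == 0)
    return(matrix(numeric(0), 0, attr(layers, "dims")[length(attr(layers, "dims"))]))
  nn_forward(layers, features)
}
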