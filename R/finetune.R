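#' Fine-tuning configuration
#'
#' Schedule and hyperparameters of the iterative pseudolabel fine-tuning
#' stage. Defaults follow the method's reference settings: fractions growing
#' from 1% to 40% of the dataset, 50 epochs per iteration at batch size 128,
#' augmentation noise level 0.1, Adam at learning rate 1e-3.
#'
#' @param fractions strictly increasing sampling fractions in (0, 1\]
#'   (default `c(0.01, 0.05, 0.10, 0.15, 0.20, 0.30, 0.40)`).
#' @param epochs_per_iter epochs per fine-tuning iteration (default 50).
#' @param batch_size minibatch size (default 128).
#' @param max_rel_noise augmentation noise level during fine-tuning
#'   (default 0.1).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param method pseudolabel sampling method (default `"weighted"`).
#' @param reestimate_k re-run the elbow estimate at each iteration
#'   (default `FALSE`: k is estimated once after pretraining and held fixed,
#'   so the classification head width never changes mid-run).
#' @param seed integer seed.
#' @return object of class `finetune_config`.
#' @export
finetune_config <- function(fractions = c(0.01, 0.05, 0.10, 0.15, 0.20, 0.30, 0.40),
                            epochs_per_iter = 50, batch_size = 128,
                            max_rel_noise = 0.1, learning_rate = 1e-3,
                            method = c("weighted", "densest"),
                            reestimate_k = FALSE, seed = 1L) {
  if (any(diff(fractions) <= 0) || any(fractions <= 0) || any(fractions > 1))
    stop_invalid("fractions must be strictly increasing within (0, 1]")
  if (epochs_per_iter < 0) stop_invalid("epochs_per_iter must be >= 0")
  structure(list(fractions = fractions,
                 epochs_per_iter = as.integer(epochs_per_iter),
                 batch_size = as.integer(batch_size),
                 max_rel_noise = max_rel_noise, learning_rate = learning_rate,
                 method = match.arg(method), reestimate_k = reestimate_k,
                 seed = as.integer(seed)),
            class = "finetune_config")
}

#' Attach a classification head to a pretrained encoder
#'
#' The encoder bottleneck is extended with a final dense layer of width `k`
#' (the putative neuron classes). Encoder weights are copied from the
#' pretrained model and remain trainable during fine-tuning. The head is
#' zero-initialized: the contrastive loss constrains only embedding
#' directions, so bottleneck magnitudes are arbitrary and a random head
#' would produce large logits whose early cross-entropy gradients destroy
#' the pretrained encoder. With a zero head the initial loss is exactly
#' `log(k)` and no gradient reaches the encoder until the head is
#' informative.
#'
#' @param encoder a `spike_encoder` from [pretrain()].
#' @param k number of classes (>= 2).
#' @param seed unused (the head is deterministic); kept for API stability.
#' @return object of class `spike_classifier` with `enc_layers`, `head`, `k`.
#' @export
build_classifier <- function(encoder, k, seed = NULL) {
  stopifnot(inherits(encoder, "spike_encoder"))
  if (k < 2) stop_invalid("k must be >= 2")
  bott <- encoder$spec$layer_dims[length(encoder$spec$layer_dims)]
  head <- structure(list(list(W = matrix(0, bott, k), b = numeric(k))),
                    dims = c(bott, as.integer(k)))
  structure(list(enc_layers = encoder$layers, head = head, k = as.integer(k),
                 spec = encoder$spec, input_scale = encoder$input_scale %||% 1,
                 loss_log = list(), fingerprint = encoder$fingerprint),
            class = "spike_classifier")
}

# class scores (logits) for a feature matrix
classifier_logits <- function(clf, features) {
  z <- nn_forward(clf$enc_layers, as.matrix(features) * (clf$input_scale %||% 1))
  nn_forward(clf$head, z)
}

#' Predict classes with a fine-tuned classifier
#'
#' @param object a `spike_classifier`.
#' @param features n x d feature matrix.
#' @param type `"class"` (0-based argmax labels) or `"prob"` (softmax matrix).
#' @param ... unused.
#' @return integer labels in `[0, k)` or an n x k probability matrix.
#' @export
predict.spike_classifier <- function(object, features, type = c("class", "prob"),
                                     ...) {
  type <- match.arg(type)
  logits <- classifier_logits(object, features)
  if (type == "class") return(max.col(logits, ties.method = "first") - 1L)
  mx <- apply(logits, 1, max)
  e <- exp(logits - mx)
  e / rowSums(e)
}

#' One fine-tuning iteration on a pseudolabeled subset
#'
#' Trains the full network (encoder and head) for `epochs_per_iter` epochs of
#' categorical cross-entropy on the pseudolabeled rows only, with Gaussian
#' feature augmentation applied to every minibatch. Adam optimizer; the mean
#' loss per epoch is appended to the classifier's `loss_log`.
#'
#' @param clf a `spike_classifier`.
#' @param features full n x d feature matrix.
#' @param pls a [assign_pseudolabels()] result (`pseudo_label_set`).
#' @param cfg a [finetune_config()].
#' @return the updated classifier.
#' @export
finetune_step <- function(clf, features, pls, cfg = finetune_config()) {
  stopifnot(inherits(clf, "spike_classifier"),
            inherits(pls, "pseudo_label_set"))
  features <- as.matrix(features)
  if (any(pls$indices < 1 | pls$indices > nrow(features)))
    stop_invalid("pseudolabel indices outside the dataset")
  if (any(pls$labels < 0 | pls$labels >= clf$k))
    stop_invalid("pseudolabel outside [0, k)")
  if (cfg$epochs_per_iter == 0) return(clf)
  X <- features[pls$indices, , drop = FALSE] * (clf$input_scale %||% 1)
  y <- pls$labels + 1L
  n <- nrow(X)
  bs <- min(cfg$batch_size, n)
  st_enc <- adam_init(clf$enc_layers); st_head <- adam_init(clf$head)
  # deep copy: Adam updates run in place and must not touch the caller's
  # (or the pretrained encoder's) weights
  enc <- copy_layers(clf$enc_layers); head <- copy_layers(clf$head)
  t_step <- 0L
  ep_loss <- numeric(cfg$epochs_per_iter)
  for (ep in seq_len(cfg$epochs_per_iter)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = bs)) {
      b <- ord[start:min(start + bs - 1L, n)]
      A <- augment(X[b, , drop = FALSE], cfg$max_rel_noise)
      fe <- nn_forward(enc, A, keep_cache = TRUE)
      fh <- nn_forward(head, fe$out, keep_cache = TRUE)
      logits <- fh$out
      mx <- apply(logits, 1, max)
      lse <- mx + log(rowSums(exp(logits - mx)))
      yi <- y[b]
      losses <- c(losses,
                  mean(lse - logits[cbind(seq_along(b), yi)]))
      P <- exp(logits - lse)
      P[cbind(seq_along(b), yi)] <- P[cbind(seq_along(b), yi)] - 1
      dLogits <- P / length(b)
      bh <- nn_backward(head, fh$cache, dLogits)
      be <- nn_backward(enc, fe$cache, bh$dX)
      t_step <- t_step + 1L
      adam_step(head, bh$grads, st_head, cfg$learning_rate, t_step)
      adam_step(enc, be$grads, st_enc, cfg$learning_rate, t_step)
    }
    ep_loss[ep] <- mean(losses)
  }
  clf$enc_layers <- enc; clf$head <- head
  clf$loss_log <- c(clf$loss_log, list(ep_loss))
  clf
}

#' Run the full self-supervised spike-sorting loop
#'
#' Executes the complete pipeline on a feature matrix: contrastive
#' pretraining, latent embedding, cluster-count estimation by the elbow
#' method on the densest 50% of the latent space (unless `k` is supplied as
#' prior knowledge), then for each fraction in the schedule: KNN density on
#' the current latent space, density-guided sampling, K-means++
#' pseudolabeling (aligned to the classification head's current predictions
#' from the second iteration on, so the persistent head trains against
#' stable class identities), one fine-tuning iteration, and re-embedding
#' with the updated encoder. Final per-spike labels are the classification
#' head's argmax over the full dataset.
#'
#' @param features n x 63 gradient feature matrix (see
#'   [normalize_and_gradient()]).
#' @param spec an [encoder_spec()].
#' @param pre_cfg a [contrastive_config()].
#' @param samp_cfg a [sampling_config()].
#' @param ft_cfg a [finetune_config()].
#' @param k optional known number of source neurons; skips the elbow estimate
#'   (mirrors benchmark protocols where the neuron count is given to every
#'   sorter).
#' @param true_labels optional ground-truth labels; when given, matched
#'   accuracy is recorded per iteration in the log.
#' @param encoder optional pre-trained `spike_encoder` to reuse (skips
#'   pretraining).
#' @return object of class `sort_result`: `labels` (0-based, length n),
#'   `k_estimate`, `iterations` (data frame with one row per scheduled
#'   fraction: fraction, n_pseudolabels, mean_loss, accuracy), `encoder_loss`,
#'   `classifier`, `fingerprint`.
#' @export
run_pseudosorter <- function(features, spec = encoder_spec(),
                             pre_cfg = contrastive_config(),
                             samp_cfg = sampling_config(),
                             ft_cfg = finetune_config(),
                             k = NULL, true_labels = NULL, encoder = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_invalid(sprintf("[%s] %s", name, conditionMessage(e))))
  }
  if (is.null(encoder))
    encoder <- stage("pretrain", pretrain(features, spec, pre_cfg))
  latent <- stage("embed", embed_all(encoder, features))
  K_dens <- max(1L, as.integer(round(samp_cfg$k_frac * n)))
  with_seed(ft_cfg$seed, {
    if (is.null(k)) {
      k <- stage("estimate_k", {
        dens <- knn_density(latent, K_dens)
        sub <- sample_densest(dens, samp_cfg$elbow_subset_fraction)
        estimate_k_elbow(latent[sub, , drop = FALSE], samp_cfg$k_search_range)
      })
    }
    clf <- stage("build_classifier", build_classifier(encoder, k))
    log_rows <- vector("list", length(ft_cfg$fractions))
    for (i in seq_along(ft_cfg$fractions)) {
      fr <- ft_cfg$fractions[i]
      it <- stage(sprintf("iteration_%d", i), {
        dens <- knn_density(latent, K_dens)
        if (ft_cfg$reestimate_k && i > 1) {
          sub <- sample_densest(dens, samp_cfg$elbow_subset_fraction)
          k_new <- estimate_k_elbow(latent[sub, , drop = FALSE],
                                    samp_cfg$k_search_range)
          if (k_new != clf$k) clf <- build_classifier(encoder, k_new)
          k <- k_new
        }
        idx <- if (ft_cfg$method == "densest") sample_densest(dens, fr)
               else sample_weighted(dens, fr, samp_cfg$decay_lambda)
        pls <- assign_pseudolabels(latent, idx, k, fraction = fr,
                                   method = ft_cfg$method)
        if (i > 1) {
          # K-means++ class identities are arbitrary per iteration; align them
          # to the persistent head's current predictions (max-agreement
          # one-to-one matching) so fine-tuning refines the same classes
          # instead of re-learning a permutation each iteration
          pred_sub <- predict(clf, features[idx, , drop = FALSE])
          conf <- table(factor(pls$labels, levels = 0:(k - 1)),
                        factor(pred_sub, levels = 0:(k - 1)))
          remap <- solve_assignment_min(-unclass(conf)) - 1L
          pls$labels <- remap[pls$labels + 1L]
        }
        pl_acc <- if (!is.null(true_labels))
          match_accuracy(pls$labels, true_labels[idx]) else NA_real_
        clf <- finetune_step(clf, features, pls, ft_cfg)
        latent <- embed_all(clf, features)
        acc <- if (!is.null(true_labels))
          match_accuracy(predict(clf, features), true_labels) else NA_real_
        last_loss <- clf$loss_log[[length(clf$loss_log)]]
        list(clf = clf, latent = latent,
             row = data.frame(iteration = i, fraction = fr,
                              n_pseudolabels = length(idx),
                              mean_loss = mean(last_loss),
                              pseudolabel_accuracy = pl_acc,
                              accuracy = acc))
      })
      clf <- it$clf; latent <- it$latent; log_rows[[i]] <- it$row
    }
    labels <- predict(clf, features)
    structure(list(labels = labels, k_estimate = as.integer(k),
                   iterations = do.call(rbind, log_rows),
                   encoder_loss = encoder$epoch_loss,
                   classifier = clf,
                   fingerprint = param_fingerprint(clf$enc_layers)),
              class = "sort_result")
  })
}

#' @export
print.sort_result <- function(x, ...) {
  cat(sprintf("<sort_result> %d spikes, k = %d, %d fine-tuning iterations\n",
              length(x$labels), x$k_estimate, nrow(x$iterations)))
  if (!all(is.na(x$iterations$accuracy)))
    cat(sprintf("  accuracy %.3f -> %.3f\n", x$iterations$accuracy[1],
                x$iterations$accuracy[nrow(x$iterations)]))
  invisible(x)
}
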