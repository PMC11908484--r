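# Hungarian algorithm (potentials + shortest augmenting path, O(n^3)) for the
# square min-cost assignment problem. cost: n x n matrix. Returns, for each
# row, the assigned column. Written here because no assignment-problem
# package is available; cluster-matching problems are tiny (k <= 20).
solve_assignment_min <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n)                 # row potentials
  v <- numeric(n + 1)             # column potentials, col 0 at index 1
  p <- integer(n + 1)             # p[j + 1] = row matched to column j
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          if (p[j + 1L] > 0) u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else minv[j + 1L] <- minv[j + 1L] - delta
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0) assignment[p[j + 1L]] <- j
  assignment
}

#' Optimally matched sorting accuracy
#'
#' Fraction of spikes correctly classified under the best one-to-one mapping
#' between predicted and true classes: the confusion matrix is matched by the
#' Hungarian (maximum-weight bipartite) algorithm and the matched diagonal is
#' divided by n. Invariant to relabeling of either argument; unmatched
#' predicted classes contribute zero (one-to-one matching, so splitting a
#' true class across several predictions is penalized).
#'
#' @param pred,true equal-length label vectors (any label alphabet).
#' @return accuracy in \[0, 1\].
#' @export
match_accuracy <- function(pred, true) {
  if (length(pred) != length(true)) stop_invalid("label length mismatch")
  if (length(pred) == 0) stop_invalid("empty label vectors")
  conf <- table(factor(pred), factor(true))
  k <- max(dim(conf))
  C <- matrix(0, k, k)
  C[seq_len(nrow(conf)), seq_len(ncol(conf))] <- conf
  assign <- solve_assignment_min(-C)
  sum(C[cbind(seq_len(k), assign)]) / length(pred)
}

#' Signed neuron-count prediction error
#'
#' `k_pred - k_true`; negative values are underestimates, the dominant
#' failure mode of cluster-count estimation on complex datasets.
#'
#' @param k_pred,k_true predicted and true source-neuron counts (>= 1).
#' @return signed integer error.
#' @export
predict_k_error <- function(k_pred, k_true) {
  if (k_pred < 1 || k_true < 1) stop_invalid("counts must be >= 1")
  as.integer(k_pred) - as.integer(k_true)
}

#' Per-spike signal-to-noise ratio
#'
#' SNR of each waveform: the absolute trough amplitude (most negative value)
#' divided by the robust noise estimate sigma_m.
#'
#' @param waveforms n x m matrix (microvolts).
#' @param sigma_m noise estimate (> 0).
#' @return nonnegative numeric vector of length n.
#' @export
spike_snr <- function(waveforms, sigma_m) {
  if (sigma_m <= 0) stop_invalid("sigma_m must be > 0")
  abs(apply(as.matrix(waveforms), 1, min)) / sigma_m
}

#' Bin SNR values into the standard reporting bins
#'
#' Bins `[4, 6)`, `[6, 8)` and `[8, Inf)`; values below 4 are labeled
#' `"<4"`.
#'
#' @param snr numeric SNR vector.
#' @return factor with levels `"<4"`, `"[4,6)"`, `"[6,8)"`, `"[8,Inf)"`.
#' @export
snr_bins <- function(snr) {
  cut(snr, breaks = c(-Inf, 4, 6, 8, Inf),
      labels = c("<4", "[4,6)", "[6,8)", "[8,Inf)"), right = FALSE)
}

#' Matched accuracy per SNR bin
#'
#' Scores the optimal one-to-one class matching on the full dataset, then
#' reports the fraction of correctly matched spikes within each SNR bin.
#'
#' @param pred,true label vectors.
#' @param snr per-spike SNR vector of the same length.
#' @return named numeric vector of per-bin accuracies (NA for empty bins).
#' @export
snr_binned_accuracy <- function(pred, true, snr) {
  if (length(pred) != length(true) || length(pred) != length(snr))
    stop_invalid("length mismatch")
  conf <- table(factor(pred), factor(true))
  k <- max(dim(conf))
  C <- matrix(0, k, k)
  C[seq_len(nrow(conf)), seq_len(ncol(conf))] <- conf
  assign <- solve_assignment_min(-C)
  # map each predicted class to its matched true class
  pl <- rownames(conf); tl <- colnames(conf)
  matched_true <- rep(NA_character_, length(pl))
  for (i in seq_along(pl))
    if (assign[i] <= length(tl)) matched_true[i] <- tl[assign[i]]
  correct <- matched_true[match(as.character(pred), pl)] == as.character(true)
  correct[is.na(correct)] <- FALSE
  tapply(correct, snr_bins(snr), mean)
}

#' PCA + Gaussian-mixture baseline sorter
#'
#' The classical reference pipeline: project waveform features onto the first
#' `n_components` principal components, then fit a k-component Gaussian
#' mixture ([mclust::Mclust]) and return its classification. Deterministic
#' under `seed` (model-based hierarchical initialization on a fixed subset).
#'
#' @param features n x d feature matrix.
#' @param k number of clusters (>= 2, <= n).
#' @param n_components PCA dimensions (default 3).
#' @param seed optional seed.
#' @return integer labels in `[0, k)`.
#' @export
baseline_pca_gmm <- function(features, k, n_components = 3, seed = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (k < 2) stop_invalid("k must be >= 2")
  if (n < k) stop_invalid("fewer points than clusters")
  run <- function() {
    nc <- min(n_components, ncol(features))
    scores <- prcomp(features, center = TRUE, scale. = FALSE)$x[, seq_len(nc),
                                                                drop = FALSE]
    init <- if (n > 2000) list(subset = sample.int(n, 2000)) else NULL
    fit <- mclust::Mclust(scores, G = k, verbose = FALSE,
                          initialization = init)
    if (is.null(fit)) stop_invalid("GMM fit failed")
    as.integer(fit$classification - 1L)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Repeated evaluation of a sorter
#'
#' Runs a sorter function several times with distinct seeds (five repeats is
#' the standard reporting protocol) and aggregates matched accuracies.
#'
#' @param sorter function `(features, seed) -> labels`.
#' @param features feature matrix passed to the sorter.
#' @param true_labels ground-truth labels.
#' @param n_runs number of repeats (default 5).
#' @param seeds seeds per run (default `seq_len(n_runs)`).
#' @return object of class `eval_report`: `per_run` accuracies,
#'   `mean_accuracy`, `sd_accuracy`, `n_runs`, `seeds`.
#' @export
repeated_eval <- function(sorter, features, true_labels, n_runs = 5,
                          seeds = seq_len(n_runs)) {
  if (n_runs < 1) stop_invalid("n_runs must be >= 1")
  if (length(seeds) != n_runs) stop_invalid("need one seed per run")
  accs <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    labels <- tryCatch(sorter(features, seeds[r]), error = function(e)
      stop_invalid(sprintf("run %d failed: %s", r, conditionMessage(e))))
    accs[r] <- match_accuracy(labels, true_labels)
  }
  structure(list(per_run = accs, mean_accuracy = mean(accs),
                 sd_accuracy = if (n_runs > 1) sd(accs) else 0,
                 n_runs = n_runs, seeds = seeds),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d runs: mean accuracy %.4f (sd %.4f)\n",
              x$n_runs, x$mean_accuracy, x$sd_accuracy))
  invisible(x)
}
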