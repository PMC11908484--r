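# Shared fixtures, built in code and cached per test run (the pretrained
# encoder is the expensive one).

.fixture_env <- new.env(parent = emptyenv())

# small labeled 2-class dataset with clearly distinct, high-SNR spikes
fixture_easy2 <- function() {
  if (is.null(.fixture_env$easy2)) {
    cfg <- sim_config(n_neurons = 2, n_spikes = 1200, noise_sigma = 3,
                      target_snr_range = c(10, 14), seed = 101)
    .fixture_env$easy2 <- normalize_and_gradient(generate_waveform_dataset(cfg))
  }
  .fixture_env$easy2
}

# encoder pretrained on the easy 2-class set (shared across embed tests)
fixture_encoder2 <- function() {
  if (is.null(.fixture_env$enc2)) {
    ws <- fixture_easy2()
    .fixture_env$enc2 <- pretrain(
      ws$features, encoder_spec(),
      contrastive_config(epochs = 6, batch_size = 128, seed = 102))
  }
  .fixture_env$enc2
}

# isotropic Gaussian blobs with the given centers (n per blob)
fixture_blobs <- function(centers, n_per, sigma = 1, seed = 1) {
  d <- ncol(centers)
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
      matrix(rnorm(n_per * d, sd = sigma), n_per, d) +
        matrix(centers[i, ], n_per, d, byrow = TRUE)))
    labels <- rep(seq_len(nrow(centers)) - 1L, each = n_per)
    list(X = X, labels = labels)
  })
}

# k well-separated blob centers (20 sigma apart) in d dimensions
blob_centers <- function(k, d = 10, sep = 20) {
  C <- matrix(0, k, d)
  for (i in seq_len(k)) C[i, ((i - 1) %% d) + 1] <- sep * ceiling(i / d)
  C
}

# brute-force matched accuracy: enumerate one-to-one assignments (k <= 6)
brute_force_accuracy <- function(pred, true) {
  pl <- sort(unique(pred)); tl <- sort(unique(true))
  conf <- as.matrix(table(factor(pred, levels = pl), factor(true, levels = tl)))
  kp <- length(pl); kt <- length(tl)
  k <- max(kp, kt)
  C <- matrix(0, k, k)
  C[seq_len(kp), seq_len(kt)] <- conf
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- 0
  for (p in perms(seq_len(k)))
    best <- max(best, sum(C[cbind(seq_len(k), p)]))
  best / length(pred)
}

# brute-force all-pairs KNN density oracle
brute_force_knn_density <- function(X, K) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  vapply(seq_len(n), function(i) {
    kd <- sort(D[i, -i], partial = K)[seq_len(K)]
    1 / max(mean(kd), 1e-12)
  }, numeric(1))
}
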