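#' Pseudolabel sampling configuration
#'
#' @param k_frac density neighborhood as a fraction of the dataset size; the
#'   KNN density uses `K = max(1, round(k_frac * n))` neighbors
#'   (default 0.005, i.e. K = 0.5% of n).
#' @param method `"weighted"` (default) or `"densest"` sampling.
#' @param decay_lambda exponential-decay rate of the weighted-sampling
#'   weights (default 5): weight `exp(-lambda * rank/n)` over density ranks,
#'   about `e^5 ~ 148:1` odds densest : sparsest while every point keeps a
#'   nonzero chance.
#' @param k_search_range cluster-count search interval for the elbow method
#'   (default `c(2, 20)`; results always clamped inside).
#' @param elbow_subset_fraction fraction of the dataset (densest sampling)
#'   on which the elbow estimate is computed (default 0.5).
#' @param seed integer seed.
#' @return object of class `sampling_config`.
#' @export
sampling_config <- function(k_frac = 0.005,
                            method = c("weighted", "densest"),
                            decay_lambda = 5.0,
                            k_search_range = c(2L, 20L),
                            elbow_subset_fraction = 0.5,
                            seed = 1L) {
  if (k_frac <= 0) stop_invalid("k_frac must be > 0")
  if (k_search_range[1] < 2 || k_search_range[2] > 20 ||
      k_search_range[1] > k_search_range[2])
    stop_invalid("k_search_range must lie within [2, 20]")
  if (elbow_subset_fraction <= 0 || elbow_subset_fraction > 1)
    stop_invalid("elbow_subset_fraction must be in (0, 1]")
  structure(list(k_frac = k_frac, method = match.arg(method),
                 decay_lambda = decay_lambda,
                 k_search_range = as.integer(k_search_range),
                 elbow_subset_fraction = elbow_subset_fraction,
                 seed = as.integer(seed)),
            class = "sampling_config")
}

#' KNN density of latent points
#'
#' Local density of each point: the inverse of its mean Euclidean distance to
#' its K nearest neighbors (self excluded). Zero mean distances (coincident
#' points) are guarded with epsilon = 1e-12, so densities stay finite and
#' strictly positive. Computed blockwise, so no full n x n matrix is held for
#' large n.
#'
#' @param latent n x d matrix (n > K).
#' @param K neighbor count (>= 1); typically 0.5% of n.
#' @return numeric density vector of length n.
#' @export
knn_density <- function(latent, K) {
  latent <- as.matrix(latent)
  n <- nrow(latent)
  K <- as.integer(K)
  if (K < 1) stop_invalid("K must be >= 1")
  if (n <= K) stop_invalid("need n > K for KNN density")
  sq <- rowSums(latent^2)
  dens <- numeric(n)
  block <- max(1L, min(n, floor(2e7 / n)))
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    # squared distances, clipped at 0 for numerical safety
    D2 <- pmax(outer(sq[idx], sq, "+") - 2 * latent[idx, , drop = FALSE] %*%
                 t(latent), 0)
    for (r in seq_along(idx)) {
      d2 <- D2[r, ]
      d2[idx[r]] <- Inf                       # exclude self by index
      kd <- sqrt(sort(d2, partial = K)[seq_len(K)])
      dens[idx[r]] <- 1 / max(mean(kd), 1e-12)
    }
  }
  dens
}

#' Densest-fraction sampling
#'
#' Returns the `ceiling(fraction * n)` indices of highest density;
#' deterministic, ties at the cut resolved by ascending index.
#'
#' @param density density vector from [knn_density()].
#' @param fraction fraction of points to take, in (0, 1].
#' @return integer vector of 1-based indices.
#' @export
sample_densest <- function(density, fraction) {
  if (fraction <= 0 || fraction > 1) stop_invalid("fraction must be in (0, 1]")
  m <- ceiling(fraction * length(density))
  order(-density, seq_along(density))[seq_len(m)]
}

#' Density-weighted sampling
#'
#' Samples `ceiling(fraction * n)` unique indices without replacement with
#' weight `exp(-decay_lambda * r_i)`, where `r_i` is the point's density rank
#' normalized to \[0, 1\] (0 = densest). High-density points are strongly
#' favored while every point keeps a nonzero selection probability, so the
#' sample still represents sparser regions.
#'
#' @inheritParams sample_densest
#' @param decay_lambda decay rate (default 5).
#' @param seed optional seed.
#' @return integer vector of unique 1-based indices.
#' @export
sample_weighted <- function(density, fraction, decay_lambda = 5.0, seed = NULL) {
  if (fraction <= 0 || fraction > 1) stop_invalid("fraction must be in (0, 1]")
  n <- length(density)
  m <- ceiling(fraction * n)
  run <- function() {
    if (m >= n) return(seq_len(n))
    r <- (rank(-density, ties.method = "first") - 1) / max(n - 1, 1)
    idx <- sample.int(n, m, replace = FALSE, prob = exp(-decay_lambda * r))
    stopifnot(!anyDuplicated(idx), all(idx >= 1 & idx <= n))
    idx
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' K-means++ clustering
#'
#' K-means with distance-proportional (++) seeding of the initial centroids,
#' Lloyd iterations via [stats::kmeans()]. Runs that end with an empty
#' cluster are restarted with a fresh seeding (up to 5 times) before the last
#' result is accepted.
#'
#' @param X n x d matrix (n >= k).
#' @param k number of clusters.
#' @param seed optional seed.
#' @param iter.max Lloyd iteration cap (default 100).
#' @return a `stats::kmeans` fit (cluster labels are 1-based as usual).
#' @export
kmeanspp <- function(X, k, seed = NULL, iter.max = 100) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < k) stop_invalid("fewer points than clusters")
  run <- function() {
    fit <- NULL
    for (attempt in 1:5) {
      centers <- kpp_seed(X, k)
      fit <- tryCatch(
        suppressWarnings(kmeans(X, centers = centers, iter.max = iter.max,
                                algorithm = "Lloyd")),
        error = function(e) NULL)
      if (!is.null(fit) && all(fit$size > 0)) return(fit)
    }
    if (is.null(fit)) stop_invalid("k-means failed: degenerate input")
    fit
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# ++ seeding: first center uniform, then prob proportional to squared
# distance to the nearest chosen center
kpp_seed <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  ci <- sample.int(n, 1)
  centers[1, ] <- X[ci, ]
  if (k > 1) {
    d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
    for (j in 2:k) {
      if (all(d2 == 0)) ci <- sample.int(n, 1)
      else ci <- sample.int(n, 1, prob = d2)
      centers[j, ] <- X[ci, ]
      d2 <- pmin(d2, rowSums((X - matrix(centers[j, ], n, ncol(X),
                                         byrow = TRUE))^2))
    }
  }
  # jitter exact duplicates so stats::kmeans accepts the centers
  if (anyDuplicated(centers))
    centers <- centers + rnorm(length(centers), 0, 1e-9)
  centers
}

#' Elbow-method cluster-count estimate
#'
#' Runs K-means++ for each k in `k_range`, records the within-cluster sum of
#' squares (the best, i.e. lowest, of `n_restarts` seedings — WCSS is a
#' minimum over partitions, so the best restart is its estimator, as in
#' `stats::kmeans`' `nstart`), and
#' returns the k with maximum perpendicular distance between the normalized
#' inertia curve and the chord joining its endpoints (Kneedle-style elbow).
#' The result is always clamped to `k_range`.
#'
#' @param latent_subset m x d matrix (m > max(k_range)).
#' @param k_range search interval, default `c(2, 20)`.
#' @param seed optional seed.
#' @param n_restarts K-means++ restarts per k (default 3).
#' @return integer cluster-count estimate in `[k_range[1], k_range[2]]`.
#' @export
estimate_k_elbow <- function(latent_subset, k_range = c(2L, 20L), seed = NULL,
                             n_restarts = 3) {
  latent_subset <- as.matrix(latent_subset)
  ks <- k_range[1]:k_range[2]
  if (nrow(latent_subset) <= max(ks))
    stop_invalid("subset smaller than the largest k in the search range")
  run <- function() {
    inertia <- vapply(ks, function(k) {
      min(vapply(seq_len(n_restarts), function(r)
        kmeanspp(latent_subset, k)$tot.withinss, numeric(1)))
    }, numeric(1))
    if (length(ks) == 1) return(ks)
    x <- (ks - ks[1]) / (ks[length(ks)] - ks[1])
    rng <- max(inertia) - min(inertia)
    if (rng == 0) return(ks[1])
    y <- (inertia - min(inertia)) / rng
    # signed distance below the chord y = 1 - x (endpoints (0,1) and (1,0))
    dist_below <- (1 - x) - y
    k_hat <- ks[which.max(dist_below)]
    max(k_range[1], min(k_range[2], k_hat))
  }
  as.integer(if (is.null(seed)) run() else with_seed(seed, run()))
}

#' Assign K-means++ pseudolabels to sampled points
#'
#' Clusters the sampled latent rows only and returns the provisional class of
#' each sampled point (0-based labels, matching the dataset layout). The best
#' of `n_restarts` K-means++ seedings (lowest within-cluster sum of squares)
#' is kept, matching the restart convention of [estimate_k_elbow()].
#'
#' @param latent full n x d latent matrix.
#' @param indices sampled 1-based row indices (unique, length >= k).
#' @param k number of pseudoclasses (>= 2).
#' @param fraction sampling fraction stored for provenance (optional).
#' @param method sampling method stored for provenance (optional).
#' @param seed optional seed.
#' @param n_restarts K-means++ restarts; the lowest-inertia fit wins
#'   (default 3).
#' @return object of class `pseudo_label_set`: `indices`, `labels` (0-based,
#'   in `[0, k)`), `k`, `fraction`, `method`.
#' @export
assign_pseudolabels <- function(latent, indices, k, fraction = NA_real_,
                                method = NA_character_, seed = NULL,
                                n_restarts = 3) {
  if (k < 2) stop_invalid("k must be >= 2")
  if (anyDuplicated(indices)) stop_invalid("sampled indices must be unique")
  if (length(indices) < k) stop_invalid("fewer sampled points than classes")
  latent <- as.matrix(latent)
  sub <- latent[indices, , drop = FALSE]
  run <- function() {
    fits <- lapply(seq_len(max(1, n_restarts)), function(r) kmeanspp(sub, k))
    fits[[which.min(vapply(fits, `[[`, numeric(1), "tot.withinss"))]]
  }
  fit <- if (is.null(seed)) run() else with_seed(seed, run())
  structure(list(indices = as.integer(indices),
                 labels = as.integer(fit$cluster - 1L),
                 k = as.integer(k), fraction = fraction, method = method),
            class = "pseudo_label_set")
}

#' @export
print.pseudo_label_set <- function(x, ...) {
  cat(sprintf("<pseudo_label_set> %d points, k = %d, fraction = %s, method = %s\n",
              length(x$indices), x$k, format(x$fraction), x$method))
  invisible(x)
}
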