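test_that("matched accuracy handles identity, relabeling and the worked case", {
  true <- c(0, 0, 1, 1, 2, 2)
  expect_equal(match_accuracy(true, true), 1)
  expect_equal(match_accuracy(c(2, 2, 0, 0, 1, 1), true), 1)
  expect_equal(match_accuracy(c(1, 1, 0, 2), c(0, 0, 1, 1)), 0.75)
  expect_error(match_accuracy(1:3, 1:4), "mismatch")
  expect_error(match_accuracy(integer(0), integer(0)), "empty")
})

test_that("matched accuracy equals brute-force assignment enumeration", {
  withr::with_seed(25, {
    for (r in 1:200) {
      k_p <- sample(2:6, 1); k_t <- sample(2:6, 1)
      n <- sample(20:60, 1)
      pred <- sample(0:(k_p - 1), n, replace = TRUE)
      true <- sample(0:(k_t - 1), n, replace = TRUE)
      expect_equal(match_accuracy(pred, true),
                   brute_force_accuracy(pred, true))
    }
  })
})

test_that("matched accuracy is invariant to relabeling either argument", {
  withr::with_seed(26, {
    pred <- sample(0:4, 300, replace = TRUE)
    true <- sample(0:4, 300, replace = TRUE)
  })
  base <- match_accuracy(pred, true)
  perm <- sample(0:4)
  expect_equal(match_accuracy(perm[pred + 1], true), base)
  expect_equal(match_accuracy(pred, perm[true + 1]), base)
})

test_that("random labels score near chance even after optimal matching", {
  k <- 4; n <- 10000
  withr::with_seed(27, {
    true <- rep(0:(k - 1), length.out = n)
    pred <- sample(0:(k - 1), n, replace = TRUE)
  })
  # 1/k plus matching inflation, bounded by 3 binomial sds
  expect_lt(match_accuracy(pred, true),
            1 / k + 3 * sqrt((1 / k) * (1 - 1 / k) / n) + 0.01)
})

test_that("neuron-count error is signed", {
  expect_identical(predict_k_error(5, 5), 0L)
  expect_identical(predict_k_error(3, 5), -2L)
  expect_identical(predict_k_error(20, 15), 5L)
  expect_error(predict_k_error(0, 3), ">= 1")
})

test_that("spike SNR uses trough amplitude over sigma_m and bins correctly", {
  w <- matrix(0, 2, 64)
  w[1, 21] <- -10
  expect_equal(spike_snr(w, 2), c(5, 0))
  expect_error(spike_snr(w, 0), "sigma_m")
  expect_identical(as.character(snr_bins(c(3.9, 4, 5.99, 6, 8, 30))),
                   c("<4", "[4,6)", "[4,6)", "[6,8)", "[8,Inf)", "[8,Inf)"))
})

test_that("simulated datasets hit their target SNR", {
  cfg <- sim_config(n_neurons = 3, n_spikes = 1000, noise_sigma = 3,
                    target_snr_range = c(8, 8), seed = 28)
  ws <- generate_waveform_dataset(cfg)
  snr <- spike_snr(ws$waveforms, ws$sigma_m)
  expect_gte(mean(snr), 7.5); expect_lte(mean(snr), 8.5)
})

test_that("the PCA-GMM baseline separates clear classes and is seeded", {
  bl <- fixture_blobs(blob_centers(2, d = 20), n_per = 200, seed = 29)
  lab <- baseline_pca_gmm(bl$X, 2, seed = 30)
  expect_gt(match_accuracy(lab, bl$labels), 0.99)
  expect_identical(baseline_pca_gmm(bl$X, 2, seed = 30), lab)
  expect_error(baseline_pca_gmm(bl$X, 1), "k must be")
  expect_error(baseline_pca_gmm(bl$X[1:3, ], 5), "fewer points")
})

test_that("repeated evaluation aggregates per-run accuracies", {
  bl <- fixture_blobs(blob_centers(2), n_per = 50, seed = 31)
  det_sorter <- function(features, seed) rep(c(0, 1), each = 50)
  rep5 <- repeated_eval(det_sorter, bl$X, bl$labels, n_runs = 5)
  expect_length(rep5$per_run, 5)
  expect_equal(rep5$sd_accuracy, 0)
  expect_gte(rep5$mean_accuracy, min(rep5$per_run))
  expect_lte(rep5$mean_accuracy, max(rep5$per_run))
  bad_sorter <- function(features, seed) stop("boom")
  expect_error(repeated_eval(bad_sorter, bl$X, bl$labels, n_runs = 2),
               "run 1")
})

test_that("SNR-binned accuracy reuses the global matching", {
  pred <- c(0, 0, 1, 1); true <- c(1, 1, 0, 0); snr <- c(5, 5, 9, 9)
  acc <- snr_binned_accuracy(pred, true, snr)
  expect_equal(unname(acc[["[4,6)"]]), 1)
  expect_equal(unname(acc[["[8,Inf)"]]), 1)
})
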