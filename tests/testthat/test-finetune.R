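test_that("classifier construction follows the head contract", {
  ws <- fixture_easy2()
  enc <- fixture_encoder2()
  expect_error(build_classifier(enc, 1), "k must be")
  clf <- build_classifier(enc, 5, seed = 34)
  probs <- predict(clf, ws$features[1:10, ], type = "prob")
  expect_identical(dim(probs), c(10L, 5L))
  expect_true(all(is.finite(probs)))
  expect_equal(rowSums(probs), rep(1, 10))
  clf2 <- build_classifier(enc, 5, seed = 34)
  expect_identical(clf$head[[1]]$W, clf2$head[[1]]$W)
})

test_that("fine-tuning learns correct pseudolabels on separable data", {
  ws <- fixture_easy2()
  enc <- fixture_encoder2()
  clf <- build_classifier(enc, 2, seed = 35)
  n <- nrow(ws$features)
  idx <- withr::with_seed(36, sample(n, round(0.1 * n)))
  pls <- structure(list(indices = idx, labels = ws$labels[idx], k = 2L,
                        fraction = 0.1, method = "given"),
                   class = "pseudo_label_set")
  cfg <- finetune_config(epochs_per_iter = 30, seed = 37)
  clf <- withr::with_seed(37, finetune_step(clf, ws$features, pls, cfg))
  train_acc <- mean(predict(clf, ws$features[idx, ]) == ws$labels[idx])
  expect_gt(train_acc, 0.99)
  # loss log recorded per epoch
  expect_length(clf$loss_log[[1]], 30)
})

test_that("zero-epoch fine-tuning leaves the classifier unchanged", {
  enc <- fixture_encoder2()
  ws <- fixture_easy2()
  clf <- build_classifier(enc, 2, seed = 38)
  pls <- structure(list(indices = 1:10, labels = rep(0:1, 5), k = 2L,
                        fraction = NA, method = "given"),
                   class = "pseudo_label_set")
  out <- finetune_step(clf, ws$features, pls, finetune_config(epochs_per_iter = 0))
  expect_identical(out$enc_layers[[1]]$W, clf$enc_layers[[1]]$W)
  expect_identical(out$head[[1]]$W, clf$head[[1]]$W)
})

test_that("fine-tuning is deterministic and validates labels", {
  ws <- fixture_easy2()
  enc <- fixture_encoder2()
  clf <- build_classifier(enc, 2, seed = 39)
  pls <- structure(list(indices = 1:200, labels = ws$labels[1:200], k = 2L,
                        fraction = NA, method = "given"),
                   class = "pseudo_label_set")
  cfg <- finetune_config(epochs_per_iter = 3)
  a <- withr::with_seed(40, finetune_step(clf, ws$features, pls, cfg))
  b <- withr::with_seed(40, finetune_step(clf, ws$features, pls, cfg))
  expect_identical(a$loss_log, b$loss_log)
  bad <- pls; bad$labels[1] <- 7L
  expect_error(finetune_step(clf, ws$features, bad, cfg), "outside")
  bad2 <- pls; bad2$indices[1] <- 10^6L
  expect_error(finetune_step(clf, ws$features, bad2, cfg), "indices")
})

test_that("fine-tuning does not mutate the pretrained encoder weights", {
  ws <- fixture_easy2()
  enc <- fixture_encoder2()
  w_before <- enc$layers[[1]]$W + 0
  clf <- build_classifier(enc, 2, seed = 41)
  pls <- structure(list(indices = 1:100, labels = ws$labels[1:100], k = 2L,
                        fraction = NA, method = "given"),
                   class = "pseudo_label_set")
  invisible(withr::with_seed(42,
    finetune_step(clf, ws$features, pls, finetune_config(epochs_per_iter = 2))))
  expect_identical(enc$layers[[1]]$W, w_before)
})

test_that("the full loop logs one entry per fraction and keeps k fixed", {
  ws <- fixture_easy2()
  enc <- fixture_encoder2()
  n <- nrow(ws$features)
  fr <- c(0.1, 0.25, 0.4)
  res <- run_pseudosorter(
    ws$features, encoder_spec(),
    samp_cfg = sampling_config(seed = 43),
    ft_cfg = finetune_config(fractions = fr, epochs_per_iter = 4, seed = 43),
    k = 2, true_labels = ws$labels, encoder = enc)
  expect_identical(nrow(res$iterations), 3L)
  expect_identical(res$iterations$fraction, fr)
  expect_identical(res$iterations$n_pseudolabels, as.integer(ceiling(fr * n)))
  expect_identical(res$k_estimate, 2L)
  expect_length(res$labels, n)
  expect_true(all(res$labels >= 0 & res$labels < 2))
  expect_false(any(is.na(res$iterations$accuracy)))
})

test_that("the elbow path of the full loop estimates k within range", {
  ws <- fixture_easy2()
  enc <- fixture_encoder2()
  res <- run_pseudosorter(
    ws$features, encoder_spec(),
    samp_cfg = sampling_config(seed = 44),
    ft_cfg = finetune_config(fractions = 0.3, epochs_per_iter = 2, seed = 44),
    encoder = enc)
  expect_gte(res$k_estimate, 2L)
  expect_lte(res$k_estimate, 20L)
})
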