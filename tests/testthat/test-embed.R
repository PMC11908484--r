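test_that("augmentation respects the relative noise contract", {
  withr::with_seed(5, X <- matrix(rnorm(200 * 63), 200))
  expect_identical(augment(X, 0), X)
  expect_identical(augment(X, 0.075, seed = 9), augment(X, 0.075, seed = 9))
  A <- augment(X, 0.075, seed = 10)
  noise <- A - X
  scale <- apply(X, 1, max) - apply(X, 1, min)
  sds <- apply(noise, 1, sd)
  # per-row noise sd is u * 0.075 * range with u ~ U(0,1): bounded by the
  # level (finite-sample slack) and roughly half of it on average
  expect_true(all(sds <= 0.075 * scale * 1.5))
  expect_lt(mean(sds / (0.075 * scale)), 0.8)
  expect_gt(mean(sds / (0.075 * scale)), 0.3)
})

test_that("contrastive loss matches the printed formula", {
  # support = positive only -> -log(1) = 0
  expect_equal(nnclr_loss(c(1, 1), matrix(c(2, 2), 1), 1, 0.1), 0)
  # orthogonal negative, tau = 0.1: log(1 + exp(-10))
  loss <- nnclr_loss(c(1, 0), rbind(c(1, 0), c(0, 1)), 1, 0.1)
  expect_lt(abs(loss - log(1 + exp(-10))), 1e-12)
  # cosine scale invariance
  withr::with_seed(6, {
    z <- rnorm(10); S <- matrix(rnorm(5 * 10), 5)
  })
  expect_equal(nnclr_loss(z, S, 2), nnclr_loss(3 * z, 7 * S, 2),
               tolerance = 1e-12)
  expect_error(nnclr_loss(rep(0, 5), matrix(1, 2, 5)), "zero-norm")
})

test_that("contrastive loss equals brute-force evaluation on random inputs", {
  brute <- function(anchor, support, pos, tau) {
    cossim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    e <- vapply(seq_len(nrow(support)),
                function(j) exp(cossim(anchor, support[j, ]) / tau),
                numeric(1))
    -log(e[pos] / sum(e))
  }
  withr::with_seed(7, {
    for (r in 1:25) {
      n <- sample(2:16, 1); d <- sample(2:10, 1)
      z <- rnorm(d); S <- matrix(rnorm(n * d), n)
      p <- sample(n, 1); tau <- runif(1, 0.05, 1)
      expect_equal(nnclr_loss(z, S, p, tau), brute(z, S, p, tau),
                   tolerance = 1e-6)
    }
  })
})

test_that("the memory queue is FIFO and fully refreshed after enough pushes", {
  qp <- asNamespace("pseudosort")$queue_push
  q <- matrix(0, 10, 2)
  ptr <- 0L
  for (step in 1:5) {
    res <- qp(q, ptr, matrix(step, 4, 2))
    q <- res$queue; ptr <- res$ptr
  }
  # 5 pushes of 4 rows into capacity 10: every slot overwritten at least once
  expect_true(all(q != 0))
  # FIFO wrap-around: slots 1-2 were last written by push 3 (rows 9,10,1,2),
  # slots 3-6 by push 4, slots 7-10 by push 5
  expect_identical(as.numeric(q[, 1]), c(3, 3, 4, 4, 4, 4, 5, 5, 5, 5))
  expect_setequal(unique(as.numeric(q)), c(3, 4, 5))
})

test_that("pretraining validates input width and is seed-reproducible", {
  ws <- fixture_easy2()
  expect_error(pretrain(ws$features[, 1:10], encoder_spec()), "input dim")
  cfg <- contrastive_config(epochs = 1, batch_size = 256, seed = 11)
  e1 <- pretrain(ws$features, encoder_spec(), cfg)
  e2 <- pretrain(ws$features, encoder_spec(), cfg)
  expect_identical(e1$epoch_loss, e2$epoch_loss)
  expect_identical(e1$layers[[1]]$W, e2$layers[[1]]$W)
})

test_that("an untrained encoder is still usable for embedding", {
  ws <- fixture_easy2()
  e0 <- pretrain(ws$features, cfg = contrastive_config(epochs = 0, seed = 12))
  expect_length(e0$epoch_loss, 0)
  lat <- embed_all(e0, ws$features)
  expect_identical(dim(lat), c(nrow(ws$features), 10L))
  expect_true(all(is.finite(lat)))
})

test_that("pretraining reduces the contrastive loss on separable data", {
  enc <- fixture_encoder2()
  expect_lt(enc$epoch_loss[length(enc$epoch_loss)], enc$epoch_loss[1])
})

test_that("embeddings are 10-dimensional, deterministic, and class-separating", {
  ws <- fixture_easy2()
  enc <- fixture_encoder2()
  lat <- embed_all(enc, ws$features)
  expect_identical(ncol(lat), 10L)
  expect_identical(embed_all(enc, ws$features[0, , drop = FALSE]),
                   matrix(numeric(0), 0, 10))
  # duplicated inputs embed identically
  dup <- embed_all(enc, ws$features[c(1, 1, 2), ])
  expect_identical(dup[1, ], dup[2, ])
  # mean between-class latent distance exceeds mean within-class distance
  idx <- seq_len(min(400, nrow(lat)))
  D <- as.matrix(dist(lat[idx, ]))
  same <- outer(ws$labels[idx], ws$labels[idx], "==")
  diag(same) <- NA
  expect_gt(mean(D[!same & !is.na(same)]), mean(D[same & !is.na(same)]))
})
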