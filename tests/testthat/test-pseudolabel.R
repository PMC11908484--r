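test_that("KNN density matches hand-computed and degenerate cases", {
  X <- matrix(c(0, 1, 2), 3, 1)
  expect_equal(knn_density(X, 1), c(1, 1, 1))
  X2 <- matrix(c(0, 1, 3), 3, 1)
  expect_equal(knn_density(X2, 1), c(1, 1, 0.5))
  # coincident points hit the epsilon guard but stay finite
  X3 <- matrix(c(0, 0, 5), 3, 1)
  d3 <- knn_density(X3, 1)
  expect_true(all(is.finite(d3)))
  expect_equal(d3[1], 1e12)
  expect_error(knn_density(X, 3), "n > K")
})

test_that("KNN density equals the brute-force all-pairs oracle", {
  withr::with_seed(13, X <- matrix(rnorm(500 * 10), 500))
  for (K in c(1, 3, 25)) {
    expect_equal(knn_density(X, K), brute_force_knn_density(X, K),
                 tolerance = 1e-10)
  }
})

test_that("densest sampling returns the exact top-fraction set", {
  expect_identical(sample_densest(c(3, 1, 2), 1 / 3), 1L)
  expect_setequal(sample_densest(c(3, 1, 2), 1), 1:3)
  # ties at the cut resolved by ascending index
  expect_identical(sample_densest(c(1, 2, 2, 2), 0.5), c(2L, 3L))
  expect_error(sample_densest(c(1, 2), 0), "fraction")
})

test_that("weighted sampling meets size, uniqueness and coverage contracts", {
  withr::with_seed(14, dens <- runif(1000))
  expect_setequal(sample_weighted(dens, 1), 1:1000)
  s <- sample_weighted(dens, 0.1, seed = 15)
  expect_length(s, 100)
  expect_false(anyDuplicated(s) > 0)
  expect_true(all(s >= 1 & s <= 1000))
  expect_identical(sample_weighted(dens, 0.1, seed = 15), s)
  # every point has nonzero selection probability: the ten sparsest points
  # (single-draw inclusion chance ~3% combined) show up within 400 seeded
  # draws with near certainty
  least10 <- order(dens)[1:10]
  hit <- any(vapply(1:400, function(sd)
    any(least10 %in% sample_weighted(dens, 0.1, seed = sd)), logical(1)))
  expect_true(hit)
})

test_that("weighted sampling is biased toward dense points", {
  # bimodal density fixture
  withr::with_seed(16, dens <- c(runif(500, 0.1, 0.3), runif(500, 5, 9)))
  wins <- vapply(1:200, function(sd)
    mean(dens[sample_weighted(dens, 0.1, seed = sd)]) > mean(dens),
    logical(1))
  expect_gte(mean(wins), 0.99)
})

test_that("densest >= weighted >= population mean density ordering holds", {
  withr::with_seed(17, dens <- rexp(800))
  md <- mean(dens[sample_densest(dens, 0.2)])
  mw <- mean(vapply(1:100, function(sd)
    mean(dens[sample_weighted(dens, 0.2, seed = sd)]), numeric(1)))
  expect_gte(md, mw)
  expect_gte(mw, mean(dens))
})

test_that("the elbow estimate recovers blob counts and respects the range", {
  for (k_true in c(3L, 5L)) {
    bl <- fixture_blobs(blob_centers(k_true), n_per = 300, seed = 18 + k_true)
    k_hat <- estimate_k_elbow(bl$X, c(2, 20), seed = 19)
    expect_identical(k_hat, k_true)
  }
  # unstructured data still yields an estimate inside [2, 20]
  withr::with_seed(20, U <- matrix(runif(600 * 10), 600))
  k_u <- estimate_k_elbow(U, c(2, 20), seed = 21)
  expect_gte(k_u, 2L); expect_lte(k_u, 20L)
  expect_error(estimate_k_elbow(U[1:10, ], c(2, 20)), "subset")
})

test_that("pseudolabel assignment recovers separated blobs exactly", {
  bl <- fixture_blobs(blob_centers(2), n_per = 150, seed = 22)
  pls <- assign_pseudolabels(bl$X, seq_len(300), 2, seed = 23)
  expect_identical(sort(unique(pls$labels)), 0:1)
  expect_equal(match_accuracy(pls$labels, bl$labels), 1)
  # determinism
  pls2 <- assign_pseudolabels(bl$X, seq_len(300), 2, seed = 23)
  expect_identical(pls$labels, pls2$labels)
  # k = number of sampled points: each point its own class
  small <- assign_pseudolabels(bl$X, 1:6, 6, seed = 24)
  expect_setequal(small$labels, 0:5)
  expect_error(assign_pseudolabels(bl$X, 1:3, 5), "fewer sampled")
  expect_error(assign_pseudolabels(bl$X, c(1, 1, 2), 2), "unique")
})
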