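test_that("well-separated blobs are recovered exactly", {
  set.seed(1)
  centers <- rbind(c(0, 0, 10), c(10, 0, 0), c(0, 10, 5))
  X <- do.call(rbind, lapply(1:3, function(k) {
    sweep(matrix(rnorm(80 * 3), 80), 2, centers[k, ], "+")
  }))
  truth <- rep(1:3, each = 80)
  cl <- cluster_samples(X, n_pcs = 3, resolution = 0.8, seed = 2)
  expect_equal(adjusted_rand_index(cl$labels, truth), 1)
  expect_equal(cl$n_clusters, 3)
})

test_that("identical rows collapse to a single cluster", {
  X <- matrix(1, 50, 4)
  cl <- cluster_samples(X, n_pcs = 2, seed = 1)
  expect_equal(cl$n_clusters, 1)
})

test_that("clustering is deterministic given the seed", {
  set.seed(3)
  X <- matrix(rnorm(200 * 6), 200)
  a <- cluster_samples(X, n_pcs = 5, resolution = 1, seed = 7)
  b <- cluster_samples(X, n_pcs = 5, resolution = 1, seed = 7)
  expect_identical(a$labels, b$labels)
})

test_that("the minimal qualifying resolution is selected", {
  set.seed(4)
  centers <- rbind(c(0, 0), c(12, 0), c(0, 12))
  X <- do.call(rbind, lapply(1:3, function(k) {
    sweep(matrix(rnorm(60 * 2), 60), 2, centers[k, ], "+")
  }))
  r <- select_resolution(X, resolutions = seq(0.1, 1, 0.1), n_pcs = 2, seed = 1)
  trace <- attr(r, "trace")
  # three balanced blobs qualify immediately: smallest candidate wins
  expect_equal(as.numeric(r), 0.1)
  expect_gte(trace$n_clusters[1], 3)
  # fallback: a two-blob structure can never satisfy >= 3 clusters at tiny resolution
  Y <- rbind(matrix(rnorm(60 * 2), 60), matrix(rnorm(60 * 2, 12), 60))
  expect_warning(
    r2 <- select_resolution(Y, resolutions = 0.01, n_pcs = 2, seed = 1),
    "constraints"
  )
  expect_equal(as.numeric(r2), 0.01)
})

test_that("ARI and AMI satisfy the hand-checked identities", {
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(0, 1, 2, 0), c(2, 0, 1, 2)), 1) # relabeling
  expect_equal(adjusted_mutual_information(c(0, 1, 2, 0), c(2, 0, 1, 2)), 1)
  # crossed pairs: brute-force pair counting is the oracle
  a <- c(0, 0, 1, 1)
  b <- c(0, 1, 0, 1)
  expect_equal(ari_brute_force(a, b), -0.5)
  expect_equal(adjusted_rand_index(a, b), ari_brute_force(a, b))
  # frozen external reference values (scikit-learn, arithmetic normalization)
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1, 2, 2), c(0, 0, 1, 1, 1, 2)),
               4 / 9, tolerance = 1e-12)
  expect_equal(adjusted_mutual_information(c(0, 0, 1, 1, 2, 2), c(0, 0, 1, 1, 1, 2)),
               0.5023607027202738, tolerance = 1e-9)
  expect_error(adjusted_rand_index(c(1, 2), c(1, 2, 3)), "length")
})

test_that("our ARI agrees with an independent implementation on random partitions", {
  skip_if_not_installed("mclust")
  set.seed(6)
  for (r in 1:20) {
    a <- sample(1:4, 100, replace = TRUE)
    b <- sample(1:3, 100, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("chance-level labelings score near zero on average", {
  set.seed(7)
  aris <- amis <- numeric(200)
  for (r in 1:200) {
    a <- sample(1:3, 500, replace = TRUE)
    b <- sample(1:3, 500, replace = TRUE)
    aris[r] <- adjusted_rand_index(a, b)
    amis[r] <- adjusted_mutual_information(a, b)
  }
  expect_lt(abs(mean(aris)), 0.02)
  expect_lt(abs(mean(amis)), 0.02)
})
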