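test_that("an empty Markov blanket reduces to the reference mean", {
  set.seed(1)
  d <- data.frame(a = rnorm(50), b = rnorm(50))
  enc <- one_hot_encode(d)
  pdag <- manual_pdag(c("a", "b")) # no edges
  models <- fit_mb_regressions(pdag, enc)
  expect_equal(models$targets$a$intercept, mean(d$a))
  expect_length(models$targets$a$coefficients, 0)
  # every treatment sample receives the same (mean) prediction
  treat <- encode_with(enc, data.frame(a = rnorm(7) + 5, b = rnorm(7)))
  pred <- predict_pseudo_control(models, treat)
  expect_equal(unname(pred["a", ]), rep(mean(d$a), 7))
})

test_that("noiseless linear structure is fit exactly", {
  set.seed(2)
  k <- rnorm(100)
  d <- data.frame(k = k, i = 2 * k)
  enc <- one_hot_encode(d)
  pdag <- manual_pdag(c("k", "i"), directed = list(c("k", "i")))
  models <- fit_mb_regressions(pdag, enc)
  expect_equal(unname(models$targets$i$coefficients["k"]), 2, tolerance = 1e-10)
  expect_equal(models$targets$i$intercept, 0, tolerance = 1e-10)
  expect_equal(models$targets$i$residual_sd, 0, tolerance = 1e-8)
})

test_that("training-sample divergence has exactly zero mean per target", {
  fx <- lowdim_fixture()
  D <- divergence_scores(fx$enc_ref, fx$models)$D
  expect_lt(max(abs(rowMeans(D))), 1e-10)
})

test_that("predictions are exactly linear in the Markov-blanket values", {
  set.seed(3)
  n <- 200
  k <- rnorm(n)
  d <- data.frame(k = k, i = 1.3 * k + rnorm(n))
  enc <- one_hot_encode(d)
  pdag <- manual_pdag(c("k", "i"), directed = list(c("k", "i")))
  models <- fit_mb_regressions(pdag, enc)
  beta <- models$targets$i$coefficients[["k"]]
  treat <- data.frame(k = rnorm(20), i = rnorm(20))
  p0 <- predict_pseudo_control(models, encode_with(enc, treat))
  shifted <- treat
  shifted$k <- shifted$k + 0.7
  p1 <- predict_pseudo_control(models, encode_with(enc, shifted))
  expect_equal(unname(p1["i", ] - p0["i", ]), rep(beta * 0.7, 20), tolerance = 1e-10)
})

test_that("adding a constant to one continuous variable leaves divergence unchanged", {
  set.seed(4)
  n <- 300
  x <- rnorm(n); y <- x + rnorm(n)
  u <- sample(1:3, n, replace = TRUE)
  ref <- data.frame(x = x, y = y, u = u)
  kinds <- c(x = "continuous", y = "continuous", u = "discrete")
  treat <- data.frame(x = rnorm(40), y = rnorm(40) + 1, u = sample(1:3, 40, TRUE))
  run <- function(shift) {
    r <- ref; t <- treat
    r$x <- r$x + shift
    t$x <- t$x + shift
    enc <- one_hot_encode(r, kinds = kinds)
    pdag <- fges(enc, pd = 1)
    m <- fit_mb_regressions(pdag, enc)
    divergence_scores(encode_with(enc, t), m)$D
  }
  expect_equal(run(0), run(10), tolerance = 1e-8)
})

test_that("penalty cross-validation handles trivial and invalid inputs", {
  set.seed(5)
  d <- data.frame(a = rnorm(120), b = rnorm(120))
  sel <- select_penalty_cv(d, pd_grid = 2, k = 3, seed = 1)
  expect_equal(sel$pd, 2)
  expect_equal(nrow(sel$cv_trace), 3) # one row per fold
  expect_error(select_penalty_cv(d, pd_grid = numeric(0)), "empty")
  expect_error(select_penalty_cv(d[1:30, ], pd_grid = 1, k = 5), "at least 20")
})

test_that("cross-validated networks predict no worse than the intercept-only model", {
  set.seed(6)
  net <- simulate_reference_network(8, 2, mean_degree = 2, seed = 17)
  ref <- sample_mixed(net, 400, seed = 18)
  enc <- one_hot_encode(ref)
  sel <- select_penalty_cv(enc, pd_grid = c(1, 4), k = 4, seed = 2)
  # held-out MSE of the selected penalty vs an empty (intercept-only) graph
  best_mse <- min(tapply(sel$cv_trace$mse, sel$cv_trace$pd, mean))
  empty_pdag <- manual_pdag(enc$variables)
  set.seed(2)
  fold <- sample(rep(1:4, length.out = nrow(enc$T)))
  empty_mse <- mean(vapply(1:4, function(f) {
    train <- lagrace:::subset_encoded(enc, fold != f)
    test <- lagrace:::subset_encoded(enc, fold == f)
    m <- fit_mb_regressions(empty_pdag, train)
    mean(divergence_scores(test, m)$D^2)
  }, numeric(1)))
  expect_lte(best_mse, empty_mse)
})
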