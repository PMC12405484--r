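test_that("reference network has the requested size and parameter ranges", {
  net <- simulate_reference_network(50, 25, mean_degree = 2, seed = 11)
  expect_equal(nrow(net$nodes), 75)
  expect_equal(nrow(net$edges), 75) # 75 * 2 / 2
  cont <- net$nodes[net$nodes$kind == "continuous", ]
  expect_true(all(cont$mu >= -1 & cont$mu <= 1))
  expect_true(all(cont$sigma >= 0.5 & cont$sigma <= 1))
  expect_true(all(net$nodes$n_levels[net$nodes$kind == "discrete"] == 4))
  w <- unlist(lapply(net$edges$W, as.vector))
  expect_true(all(w >= 0.5 & w <= 1.5))
})

test_that("degenerate and infeasible edge counts are handled", {
  empty <- simulate_reference_network(3, 0, mean_degree = 0, seed = 1)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(nrow(empty$nodes), 3)
  expect_error(
    simulate_reference_network(3, 0, mean_degree = 10, seed = 1),
    "at most"
  )
})

test_that("perturbation changes exactly the requested number of edges and stays acyclic", {
  net <- simulate_reference_network(50, 25, mean_degree = 2, seed = 3)
  key <- function(n) paste(n$edges$from, n$edges$to)
  for (s in 1:5) {
    pert <- perturb_network(net, 0.15, seed = s)
    sym_diff <- length(union(setdiff(key(net), key(pert)),
                             setdiff(key(pert), key(net))))
    expect_equal(sym_diff, round(0.15 * 75))
    expect_silent(lagrace:::validate_mixed_network(pert)) # acyclicity et al.
    expect_equal(nrow(attr(pert, "changes")), round(0.15 * 75))
  }
  expect_equal(key(perturb_network(net, 0, seed = 1)), key(net))
  # distinct seeds give pairwise distinct edge sets
  ks <- lapply(1:3, function(s) sort(key(perturb_network(net, 0.15, seed = s))))
  expect_false(identical(ks[[1]], ks[[2]]))
  expect_false(identical(ks[[1]], ks[[3]]))
  expect_false(identical(ks[[2]], ks[[3]]))
})

test_that("sampling is reproducible and respects marginal moments", {
  net <- simulate_reference_network(8, 4, mean_degree = 0, seed = 7)
  expect_identical(sample_mixed(net, 50, seed = 9), sample_mixed(net, 50, seed = 9))
  n <- 1e5
  s <- sample_mixed(net, n, seed = 2)
  for (i in which(net$nodes$kind == "continuous")) {
    id <- net$nodes$id[i]
    expect_lt(abs(mean(s[[id]]) - net$nodes$mu[i]), 4 * net$nodes$sigma[i] / sqrt(n))
  }
  # discrete no-parent marginals follow the softmax of the baseline log-odds
  for (i in which(net$nodes$kind == "discrete")) {
    id <- net$nodes$id[i]
    probs <- exp(c(net$nodes$intercepts[[i]], 0))
    probs <- probs / sum(probs)
    freq <- tabulate(s[[id]], nbins = 4) / n
    expect_true(all(abs(freq - probs) < 4 * sqrt(probs * (1 - probs) / n)))
  }
})

test_that("a single continuous edge reproduces its weight as the OLS slope", {
  net <- simulate_reference_network(2, 0, mean_degree = 1, seed = 5)
  expect_equal(nrow(net$edges), 1)
  w <- net$edges$W[[1]][1, 1]
  s <- sample_mixed(net, 1e5, seed = 4)
  fit <- lm(s[[net$edges$to[1]]] ~ s[[net$edges$from[1]]])
  est <- coef(summary(fit))[2, ]
  expect_lt(abs(est["Estimate"] - w), 3 * est["Std. Error"])
})

test_that("expression expansion keeps the exact loading count and reconstructs noiselessly", {
  set.seed(1)
  Z <- matrix(rnorm(50 * 30), 50)
  out <- expand_to_expression(Z, n_genes = 2500, sparsity_fraction = 0.01,
                              noise_sd = 1, seed = 2)
  expect_equal(sum(out$loading$A != 0), 1250) # 0.01 * 2500 * 50
  expect_equal(dim(out$expression), c(2500, 30))

  dense <- expand_to_expression(Z[1:3, , drop = FALSE], n_genes = 10,
                                sparsity_fraction = 1, noise_sd = 0, seed = 3)
  expect_equal(dense$expression, dense$loading$A %*% Z[1:3, , drop = FALSE],
               ignore_attr = TRUE)
  expect_error(expand_to_expression(Z, 100, sparsity_fraction = 0), "sparsity")
  expect_error(expand_to_expression(Z, 100, sparsity_fraction = 1.5), "sparsity")
})

test_that("benchmark studies have the configured shape and labels", {
  bench <- build_benchmark(p_cont = 10, p_disc = 5, n_ref = 120,
                           n_per_net = 40, n_perturbed = 3, seed = 6)
  expect_equal(nrow(bench$reference), 120)
  expect_equal(nrow(bench$treatment), 120)
  expect_equal(as.vector(table(bench$treatment_labels)), c(40, 40, 40))
  none <- build_benchmark(p_cont = 10, p_disc = 5, n_ref = 50,
                          n_per_net = 40, n_perturbed = 0, seed = 6)
  expect_equal(nrow(none$treatment), 0)
  hd <- build_benchmark(p_cont = 6, p_disc = 2, n_ref = 30, n_per_net = 10,
                        highdim = TRUE, n_genes = 60, sparsity = 0.2, seed = 8)
  expect_equal(dim(hd$ref_expression), c(60, 30))
  expect_equal(dim(hd$treat_expression), c(60, 30))
  expect_equal(dim(hd$Z_ref), c(6, 30))
})
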