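test_that("one-hot encoding passes continuous columns and drops the modal level", {
  d <- data.frame(
    x = rnorm(10),
    g = c(4, 4, 4, 4, 2, 2, 3, 1, 4, 4) # level 4 modal -> reference
  )
  enc <- one_hot_encode(d, kinds = c(x = "continuous", g = "discrete"))
  expect_equal(enc$T[, "x"], d$x, ignore_attr = TRUE)
  expect_equal(colnames(enc$T), c("x", "g.1", "g.2", "g.3"))
  # value 2 encodes as (0, 1, 0)
  expect_equal(unname(enc$T[5, c("g.1", "g.2", "g.3")]), c(0, 1, 0))
  # binary variable: one indicator
  b <- data.frame(z = c(0, 0, 0, 1, 1))
  encb <- one_hot_encode(b, kinds = c(z = "discrete"))
  expect_equal(ncol(encb$T), 1)
  # unseen level at transform time names variable and level
  expect_error(encode_with(enc, data.frame(x = rnorm(2), g = c(1, 7))),
               "'g'.*'7'")
  expect_error(one_hot_encode(data.frame(u = rep(1, 5)),
                              kinds = c(u = "discrete")),
               "fewer than 2")
})

test_that("DG local scores match closed-form and OLS oracles", {
  set.seed(31)
  n <- 2000
  x <- rnorm(n)
  y <- 1.5 * x + rnorm(n)
  enc <- one_hot_encode(data.frame(x = x, y = y))
  # empty parents: marginal Gaussian log-likelihood, no penalty
  s2 <- mean((y - mean(y))^2)
  expect_equal(dg_local_score(enc, "y", character(0), pd = 1),
               -(n / 2) * (log(2 * pi) + log(s2) + 1), tolerance = 1e-8)
  # one continuous parent: conditional log-likelihood from an OLS fit
  rss <- sum(resid(lm(y ~ x))^2)
  want <- -(n / 2) * (log(2 * pi) + log(rss / n) + 1) - (1 / 2) * 1 * 1 * log(n)
  expect_equal(dg_local_score(enc, "y", "x", pd = 1), want, tolerance = 1e-8)
  # self-parenting is an error
  expect_error(dg_local_score(enc, "y", "y"), "own parent")
})

test_that("an independent noise parent lowers the local score almost always", {
  hits <- 0
  for (r in 1:50) {
    set.seed(100 + r)
    n <- 1e4
    d <- data.frame(y = rnorm(n), noise = rnorm(n))
    enc <- one_hot_encode(d)
    sc <- lagrace:::dg_scorer(enc, pd = 1)
    hits <- hits + (sc("y", "noise") < sc("y", character(0)))
  }
  expect_gte(hits, 48) # >= 95% of replicates
})

test_that("greedy search recovers the exhaustively optimal CPDAG", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 5000
    x <- rnorm(n); y <- x + rnorm(n); z <- y + rnorm(n); w <- z + rnorm(n)
    chain4 <- one_hot_encode(data.frame(x = x, y = y, z = z, w = w))
    a <- rnorm(n); b <- a + rnorm(n); cc <- a + rnorm(n)
    fork <- one_hot_encode(data.frame(a = a, b = b, c = cc))
    u <- rnorm(n); v <- rnorm(n); col <- u + v + rnorm(n)
    collider <- one_hot_encode(data.frame(u = u, v = v, w = col))
    dd <- sample(1:3, n, replace = TRUE)
    m <- c(0, 1.5, -1)[dd] + rnorm(n)
    q <- m + rnorm(n)
    mixed <- one_hot_encode(data.frame(d = factor(dd), m = m, q = q))
    for (enc in list(chain4, fork, collider, mixed)) {
      g <- fges(enc, pd = 1)
      expect_true(same_pdag(g, best_cpdag_exhaustive(enc, pd = 1)))
    }
  }
})

test_that("independent columns give the empty graph", {
  set.seed(5)
  enc <- one_hot_encode(as.data.frame(matrix(rnorm(5000 * 4), ncol = 4)))
  g <- fges(enc, pd = 1)
  expect_equal(sum(g$dir) + sum(g$und), 0)
})

test_that("the total score is invariant to the choice of consistent DAG extension", {
  set.seed(8)
  n <- 4000
  x <- rnorm(n); y <- x + rnorm(n); z <- y + rnorm(n)
  enc <- one_hot_encode(data.frame(x = x, y = y, z = z))
  g <- fges(enc, pd = 1)
  vars <- g$nodes
  # all DAGs in the returned equivalence class
  in_class <- Filter(function(m) {
    cp <- lagrace:::dag_to_cpdag(m, vars)
    identical(cp$dir, g$dir) && identical(cp$und, g$und)
  }, enumerate_dags(vars))
  expect_gte(length(in_class), 2) # a chain class has several members
  scores <- vapply(in_class, function(m) {
    dag <- stats::setNames(lapply(vars, function(v) vars[m[, v]]), vars)
    dg_score_dag(enc, dag, pd = 1)
  }, numeric(1))
  expect_equal(max(scores) - min(scores), 0, tolerance = 1e-8)
  expect_equal(g$score, scores[1], tolerance = 1e-8)
})

test_that("with continuous data the DG ordering matches an lm-based Gaussian score", {
  set.seed(12)
  n <- 3000
  x <- rnorm(n); y <- x + rnorm(n); z <- x + y + rnorm(n)
  d <- data.frame(x = x, y = y, z = z)
  enc <- one_hot_encode(d)
  dags <- enumerate_dags(names(d))
  dg <- vapply(dags, function(m) {
    dag <- stats::setNames(lapply(names(d), function(v) names(d)[m[, v]]), names(d))
    dg_score_dag(enc, dag, pd = 1)
  }, numeric(1))
  # independent route: per-node OLS log-likelihood with the same penalty
  lmscore <- vapply(dags, function(m) {
    sum(vapply(names(d), function(v) {
      pa <- names(d)[m[, v]]
      f <- if (length(pa)) stats::reformulate(pa, v) else stats::as.formula(paste(v, "~ 1"))
      rss <- sum(resid(lm(f, data = d))^2)
      -(n / 2) * (log(2 * pi) + log(rss / n) + 1) - (1 / 2) * length(pa) * log(n)
    }, numeric(1)))
  }, numeric(1))
  # the two routes compute the same quantity, so values (not just ranks) agree
  expect_equal(dg, lmscore, tolerance = 1e-8)
  expect_equal(cor(rank(round(dg, 6)), rank(round(lmscore, 6))), 1)
})

test_that("returned pDAGs are closed under the orientation rules", {
  set.seed(21)
  n <- 4000
  u <- rnorm(n); v <- rnorm(n); w <- u + v + rnorm(n); t2 <- w + rnorm(n)
  enc <- one_hot_encode(data.frame(u = u, v = v, w = w, t = t2))
  g <- fges(enc, pd = 1)
  redone <- lagrace:::rebuild_cpdag(list(vars = g$nodes, dir = g$dir, und = g$und))
  expect_identical(redone$dir, g$dir)
  expect_identical(redone$und, g$und)
})

test_that("Markov blankets follow the parent/child/spouse/neighbor rule", {
  chain <- manual_pdag(c("A", "B", "C"),
                       directed = list(c("A", "B"), c("B", "C")))
  expect_setequal(markov_blanket(chain, "B"), c("A", "C"))
  collider <- manual_pdag(c("A", "Z", "Y"),
                          directed = list(c("A", "Z"), c("Y", "Z")))
  expect_setequal(markov_blanket(collider, "A"), c("Z", "Y"))
  undirected <- manual_pdag(c("A", "B", "C"), undirected = list(c("A", "B")))
  expect_setequal(markov_blanket(undirected, "A"), "B")
  expect_setequal(markov_blanket(undirected, "B"), "A")
  expect_equal(markov_blanket(undirected, "C"), character(0))
  expect_error(markov_blanket(chain, "missing"), "unknown node")
})
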