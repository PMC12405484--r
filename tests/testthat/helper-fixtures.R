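# Fixtures and independent oracles shared across test files. Everything is
# generated in code; nothing is read from disk.

# Block-structured factor data: K factors, genes_per_factor pure genes each,
# independent standard-normal factor scores, Gaussian noise.
make_block_expression <- function(K = 5, genes_per_factor = 10, n = 1000,
                                  noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  Z <- matrix(rnorm(K * n), K)
  A <- kronecker(diag(K), matrix(1, genes_per_factor, 1))
  X <- A %*% Z + noise_sd * matrix(rnorm(K * genes_per_factor * n), K * genes_per_factor)
  rownames(X) <- paste0("g", seq_len(nrow(X)))
  colnames(X) <- paste0("s", seq_len(n))
  list(X = X, Z = Z, A = A,
       pure_truth = split(rownames(X), rep(seq_len(K), each = genes_per_factor)))
}

# Exhaustive DAG enumeration over <= 4 variables (each unordered pair absent,
# forward or backward; cyclic states dropped). Independent search oracle for
# the greedy learner.
enumerate_dags <- function(vars) {
  p <- length(vars)
  prs <- t(utils::combn(p, 2))
  states <- expand.grid(rep(list(0:2), nrow(prs)))
  out <- list()
  for (r in seq_len(nrow(states))) {
    m <- matrix(FALSE, p, p, dimnames = list(vars, vars))
    for (e in seq_len(nrow(prs))) {
      st <- states[r, e]
      if (st == 1) m[prs[e, 1], prs[e, 2]] <- TRUE
      if (st == 2) m[prs[e, 2], prs[e, 1]] <- TRUE
    }
    mm <- m
    acyclic <- TRUE
    while (nrow(mm) > 0) {
      roots <- which(colSums(mm) == 0)
      if (!length(roots)) {
        acyclic <- FALSE
        break
      }
      mm <- mm[-roots, -roots, drop = FALSE]
    }
    if (acyclic) out[[length(out) + 1L]] <- m
  }
  out
}

# Globally optimal CPDAG by scoring every DAG with the decomposable score.
best_cpdag_exhaustive <- function(enc, pd = 1) {
  vars <- enc$variables
  dags <- enumerate_dags(vars)
  scores <- vapply(dags, function(m) {
    dag <- stats::setNames(lapply(vars, function(v) vars[m[, v]]), vars)
    dg_score_dag(enc, dag, pd)
  }, numeric(1))
  best <- dags[[which.max(scores)]]
  lagrace:::dag_to_cpdag(best, vars)
}

same_pdag <- function(g, cp) {
  identical(unname(g$dir), unname(cp$dir)) &&
    identical(unname(g$und), unname(cp$und))
}

# Hand-built pDAG for Markov-blanket and regression unit tests.
manual_pdag <- function(nodes, directed = NULL, undirected = NULL) {
  p <- length(nodes)
  dir <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  und <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  for (e in directed) dir[e[1], e[2]] <- TRUE
  for (e in undirected) {
    und[e[1], e[2]] <- TRUE
    und[e[2], e[1]] <- TRUE
  }
  structure(
    list(nodes = nodes, dir = dir, und = und, pd = 1, score = NA_real_),
    class = "reference_pdag"
  )
}

# Shared low-dimensional benchmark plus its learned reference network; built
# once per test run (the reference-network search is the slow step).
lowdim_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bench <- build_benchmark(
        p_cont = 50, p_disc = 25, mean_degree = 2,
        n_perturbed = 3, edge_change_fraction = 0.15,
        n_ref = 1000, n_per_net = 1000, seed = 20240901
      )
      enc_ref <- one_hot_encode(bench$reference)
      pdag <- fges(enc_ref, pd = 1)
      models <- fit_mb_regressions(pdag, enc_ref)
      cache <<- list(bench = bench, enc_ref = enc_ref, pdag = pdag, models = models)
    }
    cache
  }
})

# Brute-force adjusted Rand index by explicit pair counting (the independent
# oracle for the closed-form implementation).
ari_brute_force <- function(a, b) {
  n <- length(a)
  pairs <- utils::combn(n, 2)
  same_a <- a[pairs[1, ]] == a[pairs[2, ]]
  same_b <- b[pairs[1, ]] == b[pairs[2, ]]
  index <- sum(same_a & same_b)
  expected <- sum(same_a) * sum(same_b) / ncol(pairs)
  maximum <- (sum(same_a) + sum(same_b)) / 2
  (index - expected) / (maximum - expected)
}
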