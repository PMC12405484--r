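#' Draw samples from a mixed network by ancestral simulation
#'
#' Nodes are visited in topological order. A continuous node is its marginal
#' mean plus the weighted contributions of its parents plus Gaussian noise
#' with its stored standard deviation. A discrete node is drawn from a
#' multinomial-logistic (softmax) distribution whose level scores are the
#' node's baseline log-odds plus the weighted parent contributions; the last
#' level is the baseline with score 0. Discrete parents contribute through
#' their `n_levels - 1` level indicators, matching the encoding used for
#' network learning.
#'
#' @param net A [new_mixed_network()] object.
#' @param n Number of samples.
#' @param seed Integer seed; output is bit-reproducible.
#' @return A tibble with a `sample_id` column followed by one column per node
#'   (in topological order); discrete columns are integer levels in
#'   `1..n_levels`. Column kinds and level counts are attached as attributes
#'   `kinds` and `n_levels`.
#' @examples
#' net <- simulate_reference_network(4, 2, mean_degree = 2, seed = 1)
#' head(sample_mixed(net, 5, seed = 2))
#' @export
sample_mixed <- function(net, n, seed = 1) {
  stopifnot(inherits(net, "mixed_network"), n >= 1)
  set.seed(seed)
  nodes <- net$nodes
  edges <- net$edges
  p <- nrow(nodes)
  values <- vector("list", p)
  encodings <- vector("list", p)
  names(values) <- names(encodings) <- nodes$id

  for (i in seq_len(p)) {
    id <- nodes$id[i]
    par_edges <- which(edges$to == id)
    width <- node_enc_width(nodes, id)
    contrib <- matrix(0, n, max(width, 1L))
    for (e in par_edges) {
      contrib <- contrib + encodings[[edges$from[e]]] %*% edges$W[[e]]
    }
    if (nodes$kind[i] == "continuous") {
      y <- nodes$mu[i] + contrib[, 1L] + stats::rnorm(n, 0, nodes$sigma[i])
      values[[i]] <- y
      encodings[[i]] <- matrix(y, ncol = 1L)
    } else {
      L <- nodes$n_levels[i]
      scores <- cbind(
        sweep(contrib, 2L, nodes$intercepts[[i]], "+"),
        0
      )
      probs <- softmax_rows(scores)
      cum <- t(apply(probs, 1L, cumsum))
      u <- stats::runif(n)
      lvl <- as.integer(rowSums(u > cum) + 1L)
      lvl[lvl > L] <- L # guard against rounding at cum ~ 1
      values[[i]] <- lvl
      enc <- matrix(0, n, L - 1L)
      for (l in seq_len(L - 1L)) enc[, l] <- as.numeric(lvl == l)
      encodings[[i]] <- enc
    }
  }

  out <- tibble::as_tibble(values)
  out <- dplyr::bind_cols(tibble::tibble(sample_id = paste0("s", seq_len(n))), out)
  kinds <- stats::setNames(nodes$kind, nodes$id)
  nl <- stats::setNames(nodes$n_levels, nodes$id)
  attr(out, "kinds") <- kinds
  attr(out, "n_levels") <- nl
  out
}

#' Expand latent factor scores into high-dimensional expression
#'
#' Implements the observation model `X = A Z + E`: a dense loading matrix is
#' drawn entrywise from N(0, 1), only the `sparsity_fraction` entries with the
#' largest absolute values are retained (ties at the cutoff resolved in
#' row-major order; the retained count is exactly
#' `round(sparsity_fraction * n_genes * K)`), and independent Gaussian noise
#' with standard deviation `noise_sd` is added.
#'
#' @param Z Factor-score matrix, factors in rows (K x n_samples).
#' @param n_genes Number of observed expression features to simulate.
#' @param sparsity_fraction Fraction of loading entries retained, in (0, 1].
#' @param noise_sd Standard deviation of the additive noise (default 1).
#' @param seed Integer seed.
#' @return A list with `expression` (n_genes x n_samples, dimnames set) and
#'   `loading`, a `loading_matrix` object with fields `A` and
#'   `sparsity_fraction`.
#' @export
expand_to_expression <- function(Z, n_genes, sparsity_fraction, noise_sd = 1,
                                 seed = 1) {
  Z <- as.matrix(Z)
  if (sparsity_fraction <= 0 || sparsity_fraction > 1) {
    stop("sparsity_fraction must be in (0, 1]")
  }
  K <- nrow(Z)
  set.seed(seed)
  A <- matrix(stats::rnorm(n_genes * K), n_genes, K)
  keep_n <- round(sparsity_fraction * n_genes * K)
  ord <- order(-abs(A)) # stable: ties at the cutoff resolved by entry order
  A[ord[-seq_len(keep_n)]] <- 0
  X <- A %*% Z + noise_sd * matrix(stats::rnorm(n_genes * ncol(Z)), n_genes)
  rownames(X) <- rownames(A) <- paste0("g", seq_len(n_genes))
  colnames(A) <- rownames(Z) %||% paste0("F", seq_len(K))
  colnames(X) <- colnames(Z) %||% paste0("s", seq_len(ncol(Z)))
  loading <- structure(
    list(A = A, sparsity_fraction = sparsity_fraction),
    class = "loading_matrix"
  )
  list(expression = X, loading = loading)
}

#' @export
print.loading_matrix <- function(x, ...) {
  cat(sprintf(
    "<loading_matrix> %d genes x %d factors, %d nonzero entries (%.3g%% dense)\n",
    nrow(x$A), ncol(x$A), sum(x$A != 0), 100 * mean(x$A != 0)
  ))
  invisible(x)
}

#' Build a labelled benchmark study from the mixed-network simulator
#'
#' Simulates one reference network, `n_perturbed` independently perturbed
#' variants (each differing by `round(edge_change_fraction * n_edges)` edge
#' operations), a reference sample and a concatenated treatment sample with
#' per-sample generating-network labels. With `highdim = TRUE` the continuous
#' nodes act as latent factors and are expanded into `n_genes` observed
#' expression features through a single shared loading matrix
#' ([expand_to_expression()]).
#'
#' Defaults follow the benchmark protocol: 50 continuous + 25 discrete
#' variables at mean degree 2, three perturbed networks at a 15% edge change,
#' and 1000 samples per network; the high-dimensional variant expands to 2500
#' genes at 1% loading sparsity with unit noise.
#'
#' @param p_cont,p_disc,mean_degree,n_levels Reference-network parameters.
#' @param n_perturbed Number of perturbed (treatment) networks.
#' @param edge_change_fraction Fraction of edges modified per perturbation.
#' @param n_ref,n_per_net Reference sample size and samples per treatment net.
#' @param highdim Expand continuous nodes into expression features?
#' @param n_genes,sparsity,noise_sd High-dimensional expansion parameters.
#' @param seed Integer master seed; all stage seeds are derived from it.
#' @return A `lagrace_benchmark` list: `reference` and `treatment` sample
#'   tibbles, integer `treatment_labels` (generating network, 1-based),
#'   `networks` (reference plus perturbed, with their recorded edge changes),
#'   and in the high-dimensional variant `ref_expression`/`treat_expression`
#'   (genes x samples), the true `loading` and true factor scores
#'   `Z_ref`/`Z_treat`.
#' @export
build_benchmark <- function(p_cont = 50, p_disc = 25, mean_degree = 2,
                            n_levels = 4L,
                            n_perturbed = 3, edge_change_fraction = 0.15,
                            n_ref = 1000, n_per_net = 1000,
                            highdim = FALSE, n_genes = 2500, sparsity = 0.01,
                            noise_sd = 1, seed = 1) {
  ref_net <- simulate_reference_network(
    p_cont, p_disc, mean_degree, seed = derive_seed(seed, 1), n_levels = n_levels
  )
  nets <- list(reference = ref_net)
  reference <- sample_mixed(ref_net, n_ref, seed = derive_seed(seed, 2))
  treat_parts <- list()
  labels <- integer(0)
  for (k in seq_len(n_perturbed)) {
    pk <- perturb_network(ref_net, edge_change_fraction, seed = derive_seed(seed, 10 + k))
    nets[[paste0("perturbed", k)]] <- pk
    sk <- sample_mixed(pk, n_per_net, seed = derive_seed(seed, 20 + k))
    sk$sample_id <- paste0("t", k, "_", seq_len(n_per_net))
    treat_parts[[k]] <- sk
    labels <- c(labels, rep(k, n_per_net))
  }
  treatment <- if (length(treat_parts)) {
    out <- dplyr::bind_rows(treat_parts)
    attributes(out)$kinds <- attr(reference, "kinds")
    attributes(out)$n_levels <- attr(reference, "n_levels")
    out
  } else {
    reference[0, ]
  }
  res <- list(
    reference = reference,
    treatment = treatment,
    treatment_labels = labels,
    networks = nets,
    seed = seed
  )
  if (highdim) {
    cont_ids <- ref_net$nodes$id[ref_net$nodes$kind == "continuous"]
    Z_ref <- t(as.matrix(reference[, cont_ids]))
    Z_treat <- t(as.matrix(treatment[, cont_ids, drop = FALSE]))
    colnames(Z_ref) <- reference$sample_id
    if (ncol(Z_treat) > 0L) colnames(Z_treat) <- treatment$sample_id
    expd <- expand_to_expression(
      cbind(Z_ref, Z_treat), n_genes, sparsity, noise_sd,
      seed = derive_seed(seed, 99)
    )
    res$ref_expression <- expd$expression[, seq_len(n_ref), drop = FALSE]
    res$treat_expression <- expd$expression[, -seq_len(n_ref), drop = FALSE]
    res$loading <- expd$loading
    res$Z_ref <- Z_ref
    res$Z_treat <- Z_treat
  }
  class(res) <- "lagrace_benchmark"
  res
}

#' @export
print.lagrace_benchmark <- function(x, ...) {
  cat(sprintf(
    "<lagrace_benchmark> %d reference + %d treatment samples from %d networks%s\n",
    nrow(x$reference), nrow(x$treatment), length(x$networks),
    if (!is.null(x$ref_expression)) {
      sprintf(", expanded to %d genes", nrow(x$ref_expression))
    } else ""
  ))
  invisible(x)
}

#' Write a mixed sample to TSV with a JSON sidecar of column kinds
#'
#' @param tbl A sample tibble from [sample_mixed()].
#' @param path Output TSV path; the sidecar is written to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_sample_tsv <- function(tbl, path) {
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(
    kinds = as.list(attr(tbl, "kinds")),
    n_levels = as.list(attr(tbl, "n_levels"))
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
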