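#' Graph-based clustering of samples on divergence profiles
#'
#' Columns are mean-centered (constant columns dropped), samples are projected
#' onto the leading principal components, a k-nearest-neighbor graph is
#' built on Euclidean distance in PC space, edges are reweighted by
#' shared-nearest-neighbor (Jaccard) overlap with weak edges pruned, and the
#' standard modularity function is optimized (Louvain) at the requested
#' resolution.
#'
#' @param features Samples x features: a numeric matrix, a data frame (an
#'   optional `sample_id` column is used for names), or a
#'   `divergence_matrix` (transposed internally).
#' @param n_pcs Number of principal components (default 20; clipped with a
#'   warning when it exceeds the data dimensions).
#' @param resolution Modularity resolution parameter.
#' @param k Neighborhood size of the KNN graph (default 20, including the
#'   sample itself).
#' @param snn_prune Jaccard weights below this are removed (default 1/15).
#' @param seed Integer seed; clustering is deterministic given the seed.
#' @return A `cluster_result`: integer `labels` (0-based, ordered by
#'   decreasing cluster size), `n_clusters`, `resolution`, `n_pcs`, a 2-D
#'   `embedding` (first two PCs) and `sample_ids`.
#' @export
cluster_samples <- function(features, n_pcs = 20, resolution = 0.8, k = 20,
                            snn_prune = 1 / 15, seed = 1) {
  built <- build_snn_graph(features, n_pcs = n_pcs, k = k, snn_prune = snn_prune)
  res <- louvain_labels(built, resolution = resolution, seed = seed)
  new_cluster_result(built, res, resolution, seed)
}

new_cluster_result <- function(built, labels, resolution, seed) {
  structure(
    list(
      labels = labels,
      n_clusters = length(unique(labels)),
      resolution = resolution,
      n_pcs = built$n_pcs,
      embedding = built$embedding,
      sample_ids = built$sample_ids,
      seed = seed
    ),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result> %d samples in %d clusters (resolution %.2f, %d PCs)\n",
    length(x$labels), x$n_clusters, x$resolution, x$n_pcs
  ))
  print(table(cluster = x$labels))
  invisible(x)
}

as_feature_matrix <- function(features) {
  if (inherits(features, "divergence_matrix")) {
    return(t(features$D))
  }
  if (is.data.frame(features)) {
    ids <- if ("sample_id" %in% names(features)) features$sample_id else rownames(features)
    features$sample_id <- NULL
    m <- as.matrix(features)
    rownames(m) <- ids
    return(m)
  }
  as.matrix(features)
}

# Standardize, project to PCs and build the pruned SNN graph once; Louvain at
# different resolutions can then reuse it.
build_snn_graph <- function(features, n_pcs = 20, k = 20, snn_prune = 1 / 15) {
  X <- as_feature_matrix(features)
  if (any(!is.finite(X))) stop("features must be finite")
  n <- nrow(X)
  ids <- rownames(X) %||% paste0("s", seq_len(n))
  # center features but keep their variance: divergence targets live on
  # comparable scales and their excess variance carries the dysregulation
  # signal that clustering must see
  sds <- apply(X, 2L, stats::sd)
  X <- scale(X[, sds > 1e-12, drop = FALSE], scale = FALSE)
  if (ncol(X) == 0L) {
    # no variation at all: every sample is identical, one cluster
    return(list(graph = NULL, embedding = matrix(0, n, 2),
                n_pcs = 0L, sample_ids = ids, degenerate = TRUE))
  }
  max_pcs <- min(n - 1L, ncol(X))
  if (n_pcs > max_pcs) {
    warning(sprintf("n_pcs reduced from %d to %d (data dimensions)", n_pcs, max_pcs))
    n_pcs <- max_pcs
  }
  pcs <- pca_scores(X, n_pcs)
  k <- min(k, n)
  # k nearest neighbors (self included) in PC space
  d2 <- outer(rowSums(pcs^2), rowSums(pcs^2), "+") - 2 * tcrossprod(pcs)
  nn <- t(apply(d2, 1L, function(r) order(r)[seq_len(k)]))
  M <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k), j = as.vector(t(nn)), x = 1, dims = c(n, n)
  )
  shared <- Matrix::tcrossprod(M)
  jac <- shared / (2 * k - shared)
  jac@x[jac@x < snn_prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected", weighted = TRUE)
  list(graph = g, embedding = pcs[, seq_len(min(2L, n_pcs)), drop = FALSE],
       n_pcs = n_pcs, sample_ids = ids)
}

louvain_labels <- function(built, resolution, seed) {
  if (isTRUE(built$degenerate)) {
    return(stats::setNames(rep(0L, length(built$sample_ids)), built$sample_ids))
  }
  set.seed(seed)
  cl <- igraph::cluster_louvain(built$graph, resolution = resolution)
  memb <- igraph::membership(cl)
  # relabel 0-based by decreasing cluster size
  sizes <- sort(table(memb), decreasing = TRUE)
  remap <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  stats::setNames(as.integer(remap[as.character(memb)]), built$sample_ids)
}

# PCA scores via the smaller-side eigendecomposition (data already centered
# and scaled by the caller).
pca_scores <- function(X, n_pcs) {
  n <- nrow(X)
  p <- ncol(X)
  if (p <= n) {
    ev <- eigen(crossprod(X) / n, symmetric = TRUE)
    scores <- X %*% ev$vectors[, seq_len(n_pcs), drop = FALSE]
  } else {
    ev <- eigen(tcrossprod(X) / n, symmetric = TRUE)
    lam <- pmax(ev$values[seq_len(n_pcs)], 1e-12)
    scores <- ev$vectors[, seq_len(n_pcs), drop = FALSE] %*% diag(sqrt(lam * n), n_pcs)
  }
  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  scores
}

#' Minimal-resolution selection rule
#'
#' Scans the candidate resolutions in ascending order and returns the
#' smallest whose clustering yields at least `min_clusters` clusters with no
#' cluster holding `max_fraction` or more of the samples. When no candidate
#' qualifies the largest candidate is returned with a warning.
#'
#' @param features As in [cluster_samples()].
#' @param resolutions Ascending candidate resolutions (default 0.1–2 by 0.1).
#' @param min_clusters Minimum acceptable number of clusters (default 3).
#' @param max_fraction Largest acceptable share of any single cluster
#'   (default 0.60, exclusive).
#' @param n_pcs,k,snn_prune,seed Passed to the graph construction.
#' @return The selected resolution (numeric), with the per-candidate search
#'   trace attached as attribute `"trace"`.
#' @export
select_resolution <- function(features, resolutions = seq(0.1, 2, by = 0.1),
                              min_clusters = 3, max_fraction = 0.60,
                              n_pcs = 20, k = 20, snn_prune = 1 / 15, seed = 1) {
  if (length(resolutions) == 0L) stop("resolutions must be nonempty")
  resolutions <- sort(resolutions)
  built <- build_snn_graph(features, n_pcs = n_pcs, k = k, snn_prune = snn_prune)
  trace <- list()
  chosen <- NULL
  for (r in resolutions) {
    labels <- louvain_labels(built, resolution = r, seed = seed)
    ncl <- length(unique(labels))
    frac <- max(table(labels)) / length(labels)
    trace[[length(trace) + 1L]] <- tibble::tibble(
      resolution = r, n_clusters = ncl, max_fraction = frac
    )
    if (ncl >= min_clusters && frac < max_fraction) {
      chosen <- r
      break
    }
  }
  if (is.null(chosen)) {
    warning("no resolution met the cluster-count/size constraints; returning the largest candidate")
    chosen <- max(resolutions)
  }
  attr(chosen, "trace") <- dplyr::bind_rows(trace)
  chosen
}

#' Cluster with the minimal-resolution rule
#'
#' Convenience wrapper: [select_resolution()] followed by
#' [cluster_samples()] at the selected value, sharing one graph build.
#'
#' @inheritParams select_resolution
#' @return A `cluster_result`.
#' @export
cluster_with_rule <- function(features, resolutions = seq(0.1, 2, by = 0.1),
                              min_clusters = 3, max_fraction = 0.60,
                              n_pcs = 20, k = 20, snn_prune = 1 / 15, seed = 1) {
  built <- build_snn_graph(features, n_pcs = n_pcs, k = k, snn_prune = snn_prune)
  chosen <- NULL
  for (r in sort(resolutions)) {
    labels <- louvain_labels(built, resolution = r, seed = seed)
    ncl <- length(unique(labels))
    frac <- max(table(labels)) / length(labels)
    if (ncl >= min_clusters && frac < max_fraction) {
      chosen <- r
      break
    }
  }
  if (is.null(chosen)) {
    warning("no resolution met the cluster-count/size constraints; using the largest candidate")
    chosen <- max(resolutions)
    labels <- louvain_labels(built, resolution = chosen, seed = seed)
  }
  new_cluster_result(built, labels, chosen, seed)
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.cluster_result <- function(x, ...) {
  tibble::tibble(
    sample_id = x$sample_ids,
    cluster = unname(x$labels)
  )
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.cluster_result <- function(x, ...) {
  tibble::tibble(
    n_samples = length(x$labels),
    n_clusters = x$n_clusters,
    resolution = x$resolution,
    n_pcs = x$n_pcs,
    max_fraction = max(table(x$labels)) / length(x$labels)
  )
}

#' Scatter plot of the clustering embedding
#'
#' @param object A `cluster_result`.
#' @param ... Unused.
#' @return A ggplot object (first two PCs, colored by cluster).
#' @exportS3Method ggplot2::autoplot
autoplot.cluster_result <- function(object, ...) {
  df <- tibble::tibble(
    PC1 = object$embedding[, 1L],
    PC2 = object$embedding[, 2L],
    cluster = factor(object$labels)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2, color = .data$cluster)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::theme_minimal() +
    ggplot2::labs(color = "cluster")
}
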