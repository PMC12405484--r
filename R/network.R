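#' Mixed-type Bayesian networks for benchmark simulation
#'
#' A `mixed_network` is a directed acyclic graph over continuous and discrete
#' nodes, used as the generating model for benchmark data. Nodes are stored in
#' a topological order. Continuous nodes carry a marginal mean `mu` and noise
#' standard deviation `sigma`; discrete nodes carry `n_levels` categorical
#' levels and baseline log-odds for levels `1..n_levels-1` (the last level is
#' the baseline with log-odds 0). Every edge carries a weight matrix mapping
#' the parent's encoding (1 column for a continuous parent, `n_levels - 1`
#' indicator columns for a discrete parent) to the child's response scale
#' (1 column for a continuous child, `n_levels - 1` level scores for a
#' discrete child).
#'
#' @param nodes Tibble of node descriptors.
#' @param edges Tibble with columns `from`, `to` and a list-column `W` of
#'   weight matrices.
#' @param seed Integer seed recorded for provenance.
#' @return An object of class `mixed_network`.
#' @keywords internal
new_mixed_network <- function(nodes, edges, seed) {
  stopifnot(all(c("id", "kind", "n_levels", "mu", "sigma") %in% names(nodes)))
  net <- structure(
    list(nodes = nodes, edges = edges, seed = seed),
    class = "mixed_network"
  )
  validate_mixed_network(net)
  net
}

validate_mixed_network <- function(net) {
  nodes <- net$nodes
  edges <- net$edges
  if (anyDuplicated(nodes$id) > 0L) stop("duplicate node ids")
  if (nrow(edges) > 0L) {
    if (any(edges$from == edges$to)) stop("self loops are not allowed")
    key <- paste(edges$from, edges$to)
    if (anyDuplicated(key) > 0L) stop("duplicate edges")
    pos <- match(edges$from, nodes$id)
    pos_to <- match(edges$to, nodes$id)
    if (anyNA(pos) || anyNA(pos_to)) stop("edge endpoint not a node")
    # nodes are stored in topological order, so every edge must point forward
    if (any(pos >= pos_to)) stop("edges must respect the stored topological order")
  }
  if (any(nodes$sigma[nodes$kind == "continuous"] <= 0)) stop("sigma must be positive")
  invisible(net)
}

#' @export
print.mixed_network <- function(x, ...) {
  n_cont <- sum(x$nodes$kind == "continuous")
  n_disc <- sum(x$nodes$kind == "discrete")
  cat(sprintf(
    "<mixed_network> %d continuous + %d discrete nodes, %d edges (seed %s)\n",
    n_cont, n_disc, nrow(x$edges), format(x$seed)
  ))
  invisible(x)
}

# Width of a node's encoding when it acts as a parent, and of its response
# scale when it acts as a child.
node_enc_width <- function(nodes, id) {
  i <- match(id, nodes$id)
  if (nodes$kind[i] == "continuous") 1L else nodes$n_levels[i] - 1L
}

draw_edge_weights <- function(nodes, from, to) {
  matrix(
    stats::runif(node_enc_width(nodes, from) * node_enc_width(nodes, to), 0.5, 1.5),
    nrow = node_enc_width(nodes, from)
  )
}

#' Simulate a reference mixed network
#'
#' Draws a random DAG with `p_cont` continuous and `p_disc` discrete nodes and
#' `round((p_cont + p_disc) * mean_degree / 2)` edges. Continuous marginal
#' means are drawn from U(-1, 1), noise standard deviations from U(0.5, 1),
#' and edge weights from U(0.5, 1.5). Discrete nodes have `n_levels`
#' categories with baseline log-odds drawn from U(-1, 1). Node kinds are
#' interleaved at random positions of the topological order so that discrete
#' and continuous variables mix freely in the graph.
#'
#' @param p_cont Number of continuous nodes.
#' @param p_disc Number of discrete nodes.
#' @param mean_degree Average vertex degree of the DAG (default 2).
#' @param seed Integer seed; the draw is fully reproducible.
#' @param n_levels Number of categories for discrete nodes (default 4).
#' @return A [new_mixed_network()] object.
#' @examples
#' net <- simulate_reference_network(10, 5, mean_degree = 2, seed = 1)
#' net
#' @export
simulate_reference_network <- function(p_cont, p_disc, mean_degree = 2, seed = 1,
                                       n_levels = 4L) {
  stopifnot(p_cont >= 0, p_disc >= 0, mean_degree >= 0)
  p <- p_cont + p_disc
  if (p == 0L) stop("network needs at least one node")
  n_edges <- round(p * mean_degree / 2)
  if (n_edges > choose(p, 2)) {
    stop(sprintf(
      "requested %d edges but a DAG on %d nodes has at most %d",
      n_edges, p, choose(p, 2)
    ))
  }
  set.seed(seed)
  ids <- c(
    if (p_cont > 0L) paste0("Z", seq_len(p_cont)),
    if (p_disc > 0L) paste0("U", seq_len(p_disc))
  )
  kinds <- c(rep("continuous", p_cont), rep("discrete", p_disc))
  ord <- sample.int(p)
  ids <- ids[ord]
  kinds <- kinds[ord]
  nl <- as.integer(n_levels)
  nodes <- tibble::tibble(
    id = ids,
    kind = kinds,
    n_levels = ifelse(kinds == "discrete", nl, NA_integer_),
    mu = stats::runif(p, -1, 1),
    sigma = stats::runif(p, 0.5, 1),
    intercepts = lapply(seq_len(p), function(i) {
      if (kinds[i] == "discrete") stats::runif(nl - 1L, -1, 1) else NULL
    })
  )
  edges <- tibble::tibble(
    from = character(0), to = character(0), W = list()
  )
  if (n_edges > 0L) {
    pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
    pick <- pairs[sample.int(nrow(pairs), n_edges), , drop = FALSE]
    pick <- pick[order(pick[, 1L], pick[, 2L]), , drop = FALSE]
    edges <- tibble::tibble(
      from = ids[pick[, 1L]],
      to = ids[pick[, 2L]],
      W = lapply(seq_len(n_edges), function(k) {
        draw_edge_weights(nodes, ids[pick[k, 1L]], ids[pick[k, 2L]])
      })
    )
  }
  new_mixed_network(nodes, edges, seed)
}

#' Randomly perturb the edge set of a mixed network
#'
#' Applies `round(edge_change_fraction * n_edges)` edge operations, each
#' independently chosen as a deletion of an original edge (still present) or
#' an addition of a new acyclicity-preserving edge with freshly drawn weights.
#' Deletions only target edges of the input network and additions only create
#' pairs absent from it, so the symmetric difference between the input and
#' output edge sets equals the number of operations exactly. Node parameters
#' are untouched. The operations applied are recorded in the `"changes"`
#' attribute (a tibble with columns `op`, `from`, `to`).
#'
#' @param net A [new_mixed_network()] object.
#' @param edge_change_fraction Fraction of edges to modify, in (0, 1].
#' @param seed Integer seed.
#' @return A perturbed `mixed_network`.
#' @export
perturb_network <- function(net, edge_change_fraction, seed = 1) {
  stopifnot(inherits(net, "mixed_network"))
  if (edge_change_fraction < 0 || edge_change_fraction > 1) {
    stop("edge_change_fraction must be in [0, 1]")
  }
  n_ops <- round(edge_change_fraction * nrow(net$edges))
  set.seed(seed)
  nodes <- net$nodes
  p <- nrow(nodes)
  ids <- nodes$id
  edges <- net$edges
  orig_key <- paste(edges$from, edges$to)
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  cand_key <- paste(ids[pairs[, 1L]], ids[pairs[, 2L]])
  addable <- setdiff(cand_key, orig_key)
  deletable <- orig_key
  changes <- list()
  for (k in seq_len(n_ops)) {
    op <- sample(c("delete", "add"), 1L)
    if (op == "delete" && length(deletable) == 0L) {
      message("no original edge left to delete; drawing an addition instead")
      op <- "add"
    }
    if (op == "add" && length(addable) == 0L) {
      message("no legal addition available; drawing a deletion instead")
      op <- "delete"
    }
    if (op == "delete") {
      key <- deletable[sample.int(length(deletable), 1L)]
      deletable <- setdiff(deletable, key)
      i <- match(key, paste(edges$from, edges$to))
      changes[[k]] <- tibble::tibble(op = "delete", from = edges$from[i], to = edges$to[i])
      edges <- edges[-i, ]
    } else {
      key <- addable[sample.int(length(addable), 1L)]
      addable <- setdiff(addable, key)
      ft <- strsplit(key, " ", fixed = TRUE)[[1L]]
      edges <- dplyr::bind_rows(edges, tibble::tibble(
        from = ft[1L], to = ft[2L],
        W = list(draw_edge_weights(nodes, ft[1L], ft[2L]))
      ))
      changes[[k]] <- tibble::tibble(op = "add", from = ft[1L], to = ft[2L])
    }
  }
  # keep edges sorted by topological position for reproducible storage order
  pos <- match(edges$from, ids) * (p + 1L) + match(edges$to, ids)
  edges <- edges[order(pos), ]
  out <- new_mixed_network(nodes, edges, seed)
  attr(out, "changes") <- dplyr::bind_rows(changes)
  out
}

#' Serialize a mixed network to GraphML
#'
#' Node attributes: `kind`, `n_levels`, `mu`, `sigma`; edge attributes:
#' `weight` (mean of the edge's weight matrix) and `weights` (the full matrix,
#' JSON-encoded).
#'
#' @param net A `mixed_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = net$edges$from, to = net$edges$to),
    directed = TRUE,
    vertices = data.frame(
      name = net$nodes$id,
      kind = net$nodes$kind,
      n_levels = ifelse(is.na(net$nodes$n_levels), 0L, net$nodes$n_levels),
      mu = net$nodes$mu,
      sigma = net$nodes$sigma
    )
  )
  if (nrow(net$edges) > 0L) {
    igraph::E(g)$weight <- vapply(net$edges$W, mean, numeric(1))
    igraph::E(g)$weights <- vapply(
      net$edges$W, function(w) as.character(jsonlite::toJSON(w)), character(1)
    )
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
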