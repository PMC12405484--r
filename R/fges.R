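# Greedy equivalence search (forward insert / backward delete over CPDAGs)
# with the decomposable degenerate-Gaussian score. Graph state is a pair of
# p x p logical matrices: `dir` (dir[i, j] means i -> j) and `und`
# (symmetric, i - j). Operator definitions and validity conditions follow
# the standard two-phase equivalence-search formulation; between steps the
# modified PDAG is re-completed to a CPDAG via a consistent DAG extension
# followed by pattern + orientation-rule closure.

empty_graph_state <- function(vars) {
  p <- length(vars)
  m <- matrix(FALSE, p, p, dimnames = list(vars, vars))
  list(vars = vars, dir = m, und = m)
}

adj_mat <- function(g) g$dir | t(g$dir) | g$und

# ---- PDAG -> DAG (consistent extension, Dor & Tarsi) -----------------------

pdag_to_dag <- function(g) {
  p <- length(g$vars)
  dir <- g$dir
  und <- g$und
  dag <- g$dir
  alive <- rep(TRUE, p)
  remaining <- p
  while (remaining > 0L) {
    found <- FALSE
    adj <- dir | t(dir) | und
    for (x in which(alive)) {
      if (any(dir[x, alive])) next # x has an outgoing directed edge
      nb_und <- which(und[x, ] & alive)
      ok <- TRUE
      if (length(nb_und)) {
        ax <- which(adj[x, ] & alive)
        for (y in nb_und) {
          others <- setdiff(ax, y)
          if (length(others) && !all(adj[y, others])) {
            ok <- FALSE
            break
          }
        }
      }
      if (!ok) next
      if (length(nb_und)) dag[cbind(nb_und, x)] <- TRUE
      alive[x] <- FALSE
      dir[x, ] <- dir[, x] <- FALSE
      und[x, ] <- und[, x] <- FALSE
      remaining <- remaining - 1L
      found <- TRUE
      break
    }
    if (!found) stop("PDAG admits no consistent DAG extension")
  }
  dag
}

# ---- DAG -> CPDAG (pattern + orientation-rule closure) ---------------------

meek_closure <- function(dir, und) {
  p <- nrow(dir)
  repeat {
    changed <- FALSE
    adj <- dir | t(dir) | und
    # R1: a -> b, b - c, a and c non-adjacent  =>  b -> c
    for (b in seq_len(p)) {
      cs <- which(und[b, ])
      if (!length(cs)) next
      as <- which(dir[, b])
      if (!length(as)) next
      for (cc in cs) {
        if (!und[b, cc]) next
        if (any(!adj[as, cc])) {
          und[b, cc] <- und[cc, b] <- FALSE
          dir[b, cc] <- TRUE
          changed <- TRUE
        }
      }
    }
    # R2: a -> b -> c, a - c  =>  a -> c
    for (a in seq_len(p)) {
      cs <- which(und[a, ])
      for (cc in cs) {
        if (!und[a, cc]) next
        if (any(dir[a, ] & dir[, cc])) {
          und[a, cc] <- und[cc, a] <- FALSE
          dir[a, cc] <- TRUE
          changed <- TRUE
        }
      }
    }
    # R3: a - b, a - c, a - d, c -> b, d -> b, c and d non-adjacent  =>  a -> b
    for (a in seq_len(p)) {
      bs <- which(und[a, ])
      if (length(bs) < 1L) next
      for (b in bs) {
        if (!und[a, b]) next
        cd <- which(dir[, b] & und[a, ])
        if (length(cd) < 2L) next
        pairs <- utils::combn(cd, 2L)
        hit <- any(!adj[pairs[1L, ] + (pairs[2L, ] - 1L) * p])
        if (hit) {
          und[a, b] <- und[b, a] <- FALSE
          dir[a, b] <- TRUE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  list(dir = dir, und = und)
}

dag_to_cpdag <- function(dag, vars = colnames(dag)) {
  p <- nrow(dag)
  skel <- dag | t(dag)
  dir <- matrix(FALSE, p, p, dimnames = dimnames(dag))
  # v-structures: x -> z <- y with x, y non-adjacent stay directed
  for (z in seq_len(p)) {
    pa <- which(dag[, z])
    if (length(pa) < 2L) next
    prs <- utils::combn(pa, 2L)
    for (k in seq_len(ncol(prs))) {
      x <- prs[1L, k]; y <- prs[2L, k]
      if (!skel[x, y]) {
        dir[x, z] <- TRUE
        dir[y, z] <- TRUE
      }
    }
  }
  und <- skel & !(dir | t(dir))
  cl <- meek_closure(dir, und)
  list(vars = vars, dir = cl$dir, und = cl$und)
}

rebuild_cpdag <- function(g) {
  dag <- pdag_to_dag(g)
  dag_to_cpdag(dag, g$vars)
}

# ---- operator machinery ----------------------------------------------------

is_clique <- function(adj, members) {
  if (length(members) < 2L) return(TRUE)
  prs <- utils::combn(members, 2L)
  all(adj[cbind(prs[1L, ], prs[2L, ])])
}

# Is there a semi-directed (y ~> x) path avoiding `blocked`?
has_semidirected_path <- function(g, y, x, blocked) {
  if (y == x) return(TRUE)
  out <- g$dir | g$und
  seen <- rep(FALSE, length(g$vars))
  seen[blocked] <- TRUE
  seen[y] <- TRUE
  frontier <- y
  while (length(frontier)) {
    nxt <- which(colSums(out[frontier, , drop = FALSE]) > 0L)
    nxt <- nxt[!seen[nxt]]
    if (x %in% nxt) return(TRUE)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  FALSE
}

subsets_upto <- function(set, cap = 8L) {
  if (length(set) > cap) set <- set[seq_len(cap)]
  k <- length(set)
  out <- vector("list", 2^k)
  for (m in seq_len(2^k) - 1L) {
    out[[m + 1L]] <- set[bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) > 0L]
  }
  # order by size so smaller T / H win score ties
  out[order(lengths(out))]
}

find_best_insertion <- function(g, score, tol = 1e-10) {
  p <- length(g$vars)
  adj <- adj_mat(g)
  best <- list(gain = tol)
  # x outer, y inner: ties resolve to the lowest (source, target) pair
  for (x in seq_len(p)) {
    for (y in seq_len(p)) {
      if (x == y || adj[x, y]) next
      pa_y <- g$vars[g$dir[, y]]
      nb_y <- which(g$und[y, ])
      na_yx <- nb_y[adj[nb_y, x]]
      t0 <- nb_y[!adj[nb_y, x]]
      for (T in subsets_upto(t0)) {
        base <- union(pa_y, g$vars[c(na_yx, T)])
        gain <- score(g$vars[y], union(base, g$vars[x])) -
          score(g$vars[y], base)
        if (gain <= best$gain) next
        block <- c(na_yx, T)
        if (!is_clique(adj, block)) next
        if (has_semidirected_path(g, y, x, block)) next
        best <- list(gain = gain, x = x, y = y, T = T)
      }
    }
  }
  if (is.null(best$x)) NULL else best
}

apply_insertion <- function(g, op) {
  g$dir[op$x, op$y] <- TRUE
  for (t in op$T) {
    g$und[t, op$y] <- g$und[op$y, t] <- FALSE
    g$dir[t, op$y] <- TRUE
  }
  rebuild_cpdag(g)
}

find_best_deletion <- function(g, score, tol = 1e-10) {
  p <- length(g$vars)
  adj <- adj_mat(g)
  best <- list(gain = tol)
  for (x in seq_len(p)) {
    ys <- which(g$dir[x, ] | g$und[x, ])
    for (y in ys) {
      pa_y <- g$vars[g$dir[, y]]
      nb_y <- which(g$und[y, ])
      na_yx <- setdiff(nb_y[adj[nb_y, x]], x)
      for (H in subsets_upto(na_yx)) {
        keep <- setdiff(na_yx, H)
        if (!is_clique(adj, keep)) next
        base <- setdiff(union(pa_y, g$vars[keep]), g$vars[x])
        gain <- score(g$vars[y], base) -
          score(g$vars[y], union(base, g$vars[x]))
        if (gain <= best$gain) next
        best <- list(gain = gain, x = x, y = y, H = H)
      }
    }
  }
  if (is.null(best$x)) NULL else best
}

apply_deletion <- function(g, op) {
  x <- op$x; y <- op$y
  g$dir[x, y] <- FALSE
  g$und[x, y] <- g$und[y, x] <- FALSE
  for (h in op$H) {
    if (g$und[y, h]) {
      g$und[y, h] <- g$und[h, y] <- FALSE
      g$dir[y, h] <- TRUE
    }
    if (g$und[x, h]) {
      g$und[x, h] <- g$und[h, x] <- FALSE
      g$dir[x, h] <- TRUE
    }
  }
  rebuild_cpdag(g)
}

#' Learn a reference pDAG by greedy equivalence search with the DG score
#'
#' Starts from the empty graph, greedily applies the single edge insertion
#' that most increases the degenerate-Gaussian score until no insertion
#' helps, then greedily removes single edges while the score increases. The
#' search moves through equivalence classes (CPDAGs); the returned graph
#' contains directed edges (compelled) and undirected edges (reversible
#' within the class). Among equally scoring moves the lexicographically
#' smallest (source, target) pair with the smallest conditioning set wins,
#' making the search deterministic.
#'
#' @param enc An `encoded_table` of the reference samples
#'   ([one_hot_encode()]). Each original variable (not each indicator
#'   column) is one node.
#' @param pd Penalty discount; larger values give sparser graphs (default 1).
#' @return A `reference_pdag`: list with `nodes`, logical matrices `dir` and
#'   `und`, the `pd` used, and the total score `score` of a consistent DAG
#'   extension.
#' @examples
#' set.seed(1)
#' x <- rnorm(500); y <- x + rnorm(500)
#' enc <- one_hot_encode(data.frame(x = x, y = y))
#' fges(enc, pd = 1)
#' @export
fges <- function(enc, pd = 1) {
  stopifnot(inherits(enc, "encoded_table"))
  score <- dg_scorer(enc, pd)
  g <- empty_graph_state(enc$variables)
  repeat {
    moved <- FALSE
    repeat {
      op <- find_best_insertion(g, score)
      if (is.null(op)) break
      g <- apply_insertion(g, op)
      moved <- TRUE
    }
    repeat {
      op <- find_best_deletion(g, score)
      if (is.null(op)) break
      g <- apply_deletion(g, op)
      moved <- TRUE
    }
    if (!moved) break
  }
  dag <- pdag_to_dag(g)
  total <- sum(vapply(seq_along(g$vars), function(i) {
    score(g$vars[i], g$vars[dag[, i]])
  }, numeric(1)))
  structure(
    list(nodes = g$vars, dir = g$dir, und = g$und, pd = pd, score = total),
    class = "reference_pdag"
  )
}

#' @export
print.reference_pdag <- function(x, ...) {
  cat(sprintf(
    "<reference_pdag> %d nodes, %d directed + %d undirected edges (pd = %g, score = %.4g)\n",
    length(x$nodes), sum(x$dir), sum(x$und) / 2, x$pd, x$score
  ))
  invisible(x)
}

#' Markov blanket of a variable in a pDAG
#'
#' The union of the variable's parents, children, spouses (other parents of
#' its children) and undirected neighbors, excluding the variable itself.
#'
#' @param g A `reference_pdag` from [fges()].
#' @param v Variable name.
#' @return Character vector of variable names (possibly empty).
#' @export
markov_blanket <- function(g, v) {
  stopifnot(inherits(g, "reference_pdag"))
  i <- match(v, g$nodes)
  if (is.na(i)) stop(sprintf("unknown node '%s'", v))
  parents <- which(g$dir[, i])
  children <- which(g$dir[i, ])
  nb_und <- which(g$und[i, ])
  spouses <- integer(0)
  for (ch in children) spouses <- c(spouses, which(g$dir[, ch]))
  mb <- setdiff(unique(c(parents, children, nb_und, spouses)), i)
  g$nodes[sort(mb)]
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.reference_pdag <- function(x, ...) {
  d <- which(x$dir, arr.ind = TRUE)
  u <- which(x$und & upper.tri(x$und), arr.ind = TRUE)
  dplyr::bind_rows(
    tibble::tibble(
      from = x$nodes[d[, 1L]], to = x$nodes[d[, 2L]],
      directed = rep(TRUE, nrow(d))
    ),
    tibble::tibble(
      from = x$nodes[u[, 1L]], to = x$nodes[u[, 2L]],
      directed = rep(FALSE, nrow(u))
    )
  )
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.reference_pdag <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(x$nodes),
    n_directed = sum(x$dir),
    n_undirected = sum(x$und) / 2,
    pd = x$pd,
    score = x$score
  )
}

#' Serialize a pDAG to GraphML and a SIF-style edge list
#'
#' @param g A `reference_pdag`.
#' @param path GraphML output path; the SIF edge list is written to
#'   `paste0(path, ".sif")`.
#' @return `path`, invisibly.
#' @export
write_pdag_graphml <- function(g, path) {
  edges <- tidy.reference_pdag(g)
  ig <- igraph::graph_from_data_frame(
    d = data.frame(from = edges$from, to = edges$to, directed = edges$directed),
    directed = TRUE,
    vertices = data.frame(name = g$nodes)
  )
  igraph::write_graph(ig, path, format = "graphml")
  sif <- data.frame(
    from = edges$from,
    relation = ifelse(edges$directed, "dir", "und"),
    to = edges$to
  )
  utils::write.table(sif, paste0(path, ".sif"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
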