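#' Degenerate-Gaussian local score for mixed data
#'
#' The degenerate-Gaussian (DG) score embeds discrete variables through their
#' one-hot indicators ([one_hot_encode()]) and then treats the encoded table
#' as jointly Gaussian. The local score of variable `i` with parent set `Pa`
#' is
#' \deqn{s(T_i, T_{Pa}) = l(\hat\theta | T_{i \cup Pa}) - l(\hat\theta | T_{Pa})
#'   - \frac{PD}{2} |T_i| |T_{Pa}| \log(n)}
#' where `l` is the maximized log-likelihood of a multivariate Gaussian with
#' unrestricted mean and covariance on the given column block, `|T_i|` and
#' `|T_Pa|` are block widths, and `PD` is the penalty discount controlling
#' sparsity. The likelihood difference equals the conditional Gaussian
#' log-likelihood of block `i` given the parent block; with an empty parent
#' set the penalty term vanishes. The total score of a DAG is the sum of
#' local components, which makes the score decomposable and usable in greedy
#' equivalence search ([fges()]).
#'
#' @param enc An `encoded_table` from [one_hot_encode()].
#' @param i Variable name (an original variable, not an indicator column).
#' @param parents Character vector of parent variable names (may be empty).
#' @param pd Penalty discount (default 1); larger values give sparser graphs.
#' @return The local score (scalar).
#' @export
dg_local_score <- function(enc, i, parents = character(0), pd = 1) {
  scorer <- dg_scorer(enc, pd)
  scorer(i, parents)
}

# Closure-based scorer with memoisation; used by fges() so that repeated
# (target, parent-set) evaluations cost one hash lookup.
dg_scorer <- function(enc, pd = 1, ridge = 1e-8) {
  stopifnot(inherits(enc, "encoded_table"))
  T <- enc$T
  n <- nrow(T)
  Tc <- sweep(T, 2L, colMeans(T))
  Sigma <- crossprod(Tc) / n # MLE covariance of the encoded columns
  cmap <- enc$column_map
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  log2pi <- log(2 * pi)

  function(i, parents = character(0)) {
    if (i %in% parents) stop(sprintf("variable '%s' cannot be its own parent", i))
    if (!i %in% names(cmap)) stop(sprintf("unknown variable '%s'", i))
    parents <- sort(parents)
    key <- paste(i, paste(parents, collapse = ","), sep = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    ci <- cmap[[i]]
    cp <- unlist(cmap[parents], use.names = FALSE)
    wi <- length(ci)
    wp <- length(cp)
    ld_joint <- logdet_psd(Sigma[c(ci, cp), c(ci, cp), drop = FALSE], ridge)
    ld_pa <- if (wp > 0L) logdet_psd(Sigma[cp, cp, drop = FALSE], ridge) else 0
    ll_diff <- -(n / 2) * (wi * log2pi + ld_joint - ld_pa + wi)
    val <- ll_diff - (pd / 2) * wi * wp * log(n)
    cache[[key]] <- val
    val
  }
}

#' Total DG score of a DAG
#'
#' Sums the local scores of every variable given its parents in `dag`.
#'
#' @param enc An `encoded_table`.
#' @param dag Named list mapping each variable to its character vector of
#'   parents (variables absent from the list have no parents).
#' @param pd Penalty discount.
#' @return Total score (scalar).
#' @export
dg_score_dag <- function(enc, dag, pd = 1) {
  scorer <- dg_scorer(enc, pd)
  sum(vapply(
    enc$variables,
    function(v) scorer(v, dag[[v]] %||% character(0)),
    numeric(1)
  ))
}
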