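#' Overlapping latent-factor discovery from expression (pure-variable model)
#'
#' Fits the identifiable overlapping factor model `X = A Z + E` to a
#' genes-by-samples expression matrix. Identifiability rests on every latent
#' factor having at least two *pure* genes — genes loading on that factor
#' alone. The fit proceeds in three stages for each candidate tuning value
#' `delta`:
#'
#' 1. **Pure-variable detection.** Genes are standardized and their
#'    correlation matrix computed. A gene `i` is declared pure when every gene
#'    whose absolute correlation with `i` comes within `2 * delta` of `i`'s
#'    maximum has an absolute-correlation profile uniformly within
#'    `2 * delta` of `i`'s own (pure genes of one factor have proportional
#'    covariance rows). Pure genes are grouped into factors by mutual
#'    membership of these near-maximum sets; groups of fewer than two genes
#'    are discarded.
#' 2. **Loading estimation.** Pure rows of `A` are set to the recovered signs;
#'    the factor covariance `C` is estimated from pure-pure correlations, and
#'    mixed rows by solving `C a_i = h_i` where `h_i` averages gene `i`'s
#'    correlation with each pure group. Mixed-row entries below `delta` in
#'    magnitude are set to zero.
#' 3. **Score estimation.** `Z` is the least-squares projection of the
#'    standardized data on `A`.
#'
#' `delta` is selected by minimizing a Gaussian-residual AIC
#' ([aic_score()]); the number of factors `K` is determined by the data, not
#' fixed by the user.
#'
#' @param X Expression matrix, genes in rows, samples in columns (a matrix or
#'   data frame with gene row names). Constant genes are dropped with a
#'   warning.
#' @param delta_grid Numeric vector of candidate `delta` values. Default: 21
#'   log-spaced values spanning `sqrt(log(p) / n)` times `0.3`–`30`.
#' @param loading_threshold Hard threshold applied to mixed-row loadings
#'   (default 0.5). Pure rows have magnitude 1 by construction, so the
#'   default discards mixed memberships weaker than half a pure loading;
#'   estimated mixed coefficients below this level are dominated by
#'   estimation noise (amplified by the inverse factor covariance) and a
#'   looser threshold produces spuriously dense loadings whose shared noise
#'   then contaminates every downstream step.
#' @return A `love_fit` object with elements `A` (genes x K), `Z_ref`
#'   (K x n_ref), `pure_sets` (list of gene-id vectors), `delta`, `aic`,
#'   `rss`, `trace` (one row per grid value), and the reference
#'   standardization (`center`, `scale`).
#' @examples
#' set.seed(1)
#' Z <- matrix(rnorm(3 * 200), 3)
#' A <- kronecker(diag(3), matrix(1, 4, 1))
#' X <- A %*% Z + 0.1 * matrix(rnorm(12 * 200), 12)
#' rownames(X) <- paste0("g", 1:12)
#' fit <- fit_love(X)
#' glance(fit)
#' @export
fit_love <- function(X, delta_grid = NULL, loading_threshold = 0.5) {
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- paste0("g", seq_len(nrow(X)))
  if (ncol(X) < 2L) stop("need at least 2 samples")
  n <- ncol(X)
  ctr <- rowMeans(X)
  Xc <- X - ctr
  scl <- sqrt(rowMeans(Xc^2))
  const <- scl <= 1e-12
  if (any(const)) {
    warning(sprintf("dropping %d constant gene(s)", sum(const)))
    X <- X[!const, , drop = FALSE]
    Xc <- Xc[!const, , drop = FALSE]
    ctr <- ctr[!const]
    scl <- scl[!const]
  }
  p <- nrow(X)
  Xs <- Xc / scl
  Sigma <- tcrossprod(Xs) / n
  if (is.null(delta_grid)) {
    base <- sqrt(log(max(p, 2)) / n)
    delta_grid <- base * exp(seq(log(0.3), log(30), length.out = 21))
  }

  AbsS <- abs(Sigma)
  fits <- vector("list", length(delta_grid))
  trace <- vector("list", length(delta_grid))
  for (d in seq_along(delta_grid)) {
    delta <- delta_grid[d]
    fit <- love_fit_one(Xs, Sigma, AbsS, delta, loading_threshold)
    fits[[d]] <- fit
    trace[[d]] <- tibble::tibble(
      delta = delta,
      K = if (is.null(fit)) 0L else ncol(fit$A),
      rss = if (is.null(fit)) NA_real_ else fit$rss,
      n_nonzero = if (is.null(fit)) NA_integer_ else sum(fit$A != 0),
      aic = if (is.null(fit)) NA_real_ else fit$aic
    )
  }
  trace <- dplyr::bind_rows(trace)
  if (all(trace$K == 0L)) {
    stop(sprintf(
      "no delta in the grid [%s] yields at least one factor",
      paste(signif(delta_grid, 3), collapse = ", ")
    ))
  }
  best <- which.min(trace$aic)
  fit <- fits[[best]]
  structure(
    list(
      A = fit$A, Z_ref = fit$Z, pure_sets = fit$pure_sets,
      delta = delta_grid[best], aic = trace$aic[best], rss = fit$rss,
      trace = trace, center = ctr, scale = scl, gene_ids = rownames(X),
      n_samples = n
    ),
    class = "love_fit"
  )
}

# One LOVE fit at a fixed delta on pre-standardized data. Returns NULL when no
# factor (pure group of size >= 2) is found.
love_fit_one <- function(Xs, Sigma, AbsS, delta, loading_threshold) {
  p <- nrow(Sigma)
  n <- ncol(Xs)
  diagless <- AbsS
  diag(diagless) <- -Inf
  M <- apply(diagless, 1L, max)
  cand <- which(M > 2 * delta)
  pure <- logical(p)
  Slist <- vector("list", p)
  for (i in cand) {
    Si <- which(diagless[i, ] >= M[i] - 2 * delta)
    Slist[[i]] <- Si
    D <- abs(AbsS[Si, , drop = FALSE] -
               matrix(AbsS[i, ], length(Si), p, byrow = TRUE))
    D[, i] <- 0
    D[cbind(seq_along(Si), Si)] <- 0
    pure[i] <- max(D) <= 2 * delta
  }
  pure_idx <- which(pure)
  if (length(pure_idx) < 2L) return(NULL)

  # group pure genes by mutual near-maximum membership
  adj <- lapply(pure_idx, function(i) {
    j <- intersect(Slist[[i]], pure_idx)
    j[vapply(j, function(jj) i %in% Slist[[jj]], logical(1))]
  })
  names(adj) <- as.character(pure_idx)
  group <- stats::setNames(rep(NA_integer_, length(pure_idx)), as.character(pure_idx))
  sign_of <- stats::setNames(rep(NA_real_, length(pure_idx)), as.character(pure_idx))
  g <- 0L
  for (i in pure_idx) {
    key <- as.character(i)
    if (!is.na(group[key])) next
    g <- g + 1L
    queue <- i
    group[key] <- g
    sign_of[key] <- 1
    while (length(queue)) {
      cur <- queue[1L]
      queue <- queue[-1L]
      for (j in adj[[as.character(cur)]]) {
        kj <- as.character(j)
        if (is.na(group[kj])) {
          group[kj] <- g
          sign_of[kj] <- sign_of[as.character(cur)] * sign(Sigma[cur, j])
          queue <- c(queue, j)
        }
      }
    }
  }
  groups <- split(pure_idx, group[as.character(pure_idx)])
  keep <- vapply(groups, length, integer(1)) >= 2L
  groups <- groups[keep]
  K <- length(groups)
  if (K == 0L) return(NULL)

  # signed membership matrix of pure genes
  G <- matrix(0, p, K)
  for (k in seq_len(K)) {
    m <- groups[[k]]
    G[m, k] <- sign_of[as.character(m)]
  }
  sizes <- vapply(groups, length, numeric(1))
  GtSG <- crossprod(G, Sigma %*% G)
  C <- GtSG / outer(sizes, sizes)
  for (k in seq_len(K)) {
    m <- groups[[k]]
    C[k, k] <- (GtSG[k, k] - sum(diag(Sigma)[m])) / (sizes[k] * (sizes[k] - 1))
  }
  C <- (C + t(C)) / 2

  A <- matrix(0, p, K, dimnames = list(rownames(Sigma), paste0("F", seq_len(K))))
  pure_all <- unlist(groups, use.names = FALSE)
  A[cbind(pure_all, rep(seq_len(K), sizes))] <- sign_of[as.character(pure_all)]
  mixed <- setdiff(seq_len(p), pure_all)
  if (length(mixed)) {
    H <- (Sigma[mixed, , drop = FALSE] %*% G) / matrix(sizes, length(mixed), K, byrow = TRUE)
    Creg <- C + diag(1e-8, K)
    Am <- t(solve(Creg, t(H)))
    Am[abs(Am) < loading_threshold] <- 0
    A[mixed, ] <- Am
  }

  Z <- solve(crossprod(A) + diag(1e-8, K), crossprod(A, Xs))
  rss <- sum((Xs - A %*% Z)^2)
  aic <- aic_score(rss, p, n, sum(A != 0), K)
  list(
    A = A, Z = Z, rss = rss, aic = aic,
    pure_sets = lapply(groups, function(m) rownames(Sigma)[m])
  )
}

#' Gaussian-residual AIC for a factor fit
#'
#' `AIC = n_genes * n_samples * log(RSS / (n_genes * n_samples)) +
#'  2 * (n_nonzero + K)`, where `n_nonzero` counts nonzero loading entries.
#' Lower is better. A zero residual is guarded to a large negative sentinel.
#'
#' @param rss Residual sum of squares of the reconstruction.
#' @param n_genes,n_samples Data dimensions.
#' @param n_nonzero Number of nonzero entries of the loading matrix.
#' @param k Number of factors.
#' @return The AIC value (scalar).
#' @export
aic_score <- function(rss, n_genes, n_samples, n_nonzero, k) {
  m <- n_genes * n_samples
  if (rss <= 0) {
    message("zero residual in AIC; returning large negative sentinel")
    return(-1e12 + 2 * (n_nonzero + k))
  }
  m * log(rss / m) + 2 * (n_nonzero + k)
}

#' Project new samples onto a fitted loading matrix
#'
#' Standardizes `X_new` with the reference genes' means and scales and solves
#' the per-sample least-squares problem `min_z || x - A z ||^2` against the
#' reference loading matrix. Rank-deficient `A` falls back to the
#' minimum-norm solution (with a message).
#'
#' @param model A [fit_love()] object.
#' @param X_new Expression matrix with the fitted genes in rows (matched by
#'   row name; missing genes are an error).
#' @return A `factor_scores` object: list with `Z` (K x n_samples) and
#'   `sample_ids`.
#' @export
project_factors <- function(model, X_new) {
  stopifnot(inherits(model, "love_fit"))
  X_new <- as.matrix(X_new)
  if (is.null(rownames(X_new))) {
    if (nrow(X_new) != length(model$gene_ids)) {
      stop("X_new lacks row names and its gene count differs from the fit")
    }
    rownames(X_new) <- model$gene_ids
  }
  missing <- setdiff(model$gene_ids, rownames(X_new))
  if (length(missing)) {
    stop(sprintf(
      "X_new is missing %d fitted gene(s), e.g. %s",
      length(missing), paste(utils::head(missing, 3), collapse = ", ")
    ))
  }
  X_new <- X_new[model$gene_ids, , drop = FALSE]
  Xs <- (X_new - model$center) / model$scale
  A <- model$A
  AtA <- crossprod(A)
  Z <- tryCatch(
    solve(AtA, crossprod(A, Xs)),
    error = function(e) {
      message("rank-deficient loading matrix; using minimum-norm projection")
      pinv_solve(A, Xs)
    }
  )
  rownames(Z) <- colnames(A)
  structure(
    list(Z = Z, sample_ids = colnames(X_new) %||% paste0("s", seq_len(ncol(Xs)))),
    class = "factor_scores"
  )
}

#' @export
print.love_fit <- function(x, ...) {
  cat(sprintf(
    "<love_fit> K = %d factors over %d genes (delta = %.4g, AIC = %.4g)\n",
    ncol(x$A), nrow(x$A), x$delta, x$aic
  ))
  invisible(x)
}

#' @export
print.factor_scores <- function(x, ...) {
  cat(sprintf("<factor_scores> %d factors x %d samples\n", nrow(x$Z), ncol(x$Z)))
  invisible(x)
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.love_fit <- function(x, ...) {
  A <- x$A
  tibble::tibble(
    gene = rep(rownames(A), ncol(A)),
    factor = rep(colnames(A), each = nrow(A)),
    loading = as.vector(A)
  ) |>
    dplyr::filter(.data$loading != 0) |>
    dplyr::mutate(
      pure = purrr::map2_lgl(.data$gene, .data$factor, function(g, f) {
        k <- match(f, colnames(A))
        k <= length(x$pure_sets) && g %in% x$pure_sets[[k]]
      })
    )
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.love_fit <- function(x, ...) {
  tibble::tibble(
    n_factors = ncol(x$A),
    n_genes = nrow(x$A),
    n_samples = x$n_samples,
    delta = x$delta,
    aic = x$aic,
    rss = x$rss
  )
}
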