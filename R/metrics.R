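#' Adjusted Rand index between two partitions
#'
#' Chance-adjusted pair-counting agreement under the permutation model:
#' `(Index - Expected) / (Max - Expected)` where the index counts sample
#' pairs co-clustered in both partitions. Invariant to label permutation;
#' equals 1 iff the partitions are identical up to relabeling; 0 in
#' expectation for independent labelings.
#'
#' @param labels_a,labels_b Vectors of cluster labels, equal length >= 2.
#' @return The ARI (scalar).
#' @examples
#' adjusted_rand_index(c(0, 0, 1, 1), c(1, 1, 0, 0)) # 1
#' adjusted_rand_index(c(0, 0, 1, 1), c(0, 1, 0, 1)) # -0.5
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  check_label_args(labels_a, labels_b)
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  expected <- sa * sb / choose(n, 2)
  maximum <- (sa + sb) / 2
  if (abs(maximum - expected) < .Machine$double.eps) {
    return(1) # both partitions degenerate and identical in structure
  }
  (sum_ij - expected) / (maximum - expected)
}

#' Adjusted mutual information between two partitions
#'
#' Mutual information corrected for chance under the hypergeometric
#' permutation model and normalized by the arithmetic mean of the two
#' entropies: `(MI - E[MI]) / (mean(H_a, H_b) - E[MI])`. Invariant to label
#' permutation; 1 iff the partitions are identical up to relabeling.
#'
#' @inheritParams adjusted_rand_index
#' @return The AMI (scalar).
#' @export
adjusted_mutual_information <- function(labels_a, labels_b) {
  check_label_args(labels_a, labels_b)
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  ai <- rowSums(tab)
  bj <- colSums(tab)
  if (length(ai) == 1L && length(bj) == 1L) return(1)
  if (length(ai) == n && length(bj) == n) return(1)
  pa <- ai / n
  pb <- bj / n
  ha <- -sum(pa * log(pa))
  hb <- -sum(pb * log(pb))
  P <- tab / n
  mi <- sum(ifelse(P > 0, P * log(P / outer(pa, pb)), 0))
  emi <- expected_mutual_information(ai, bj, n)
  denominator <- (ha + hb) / 2 - emi
  eps <- .Machine$double.eps
  denominator <- if (denominator < 0) min(denominator, -eps) else max(denominator, eps)
  as.numeric((mi - emi) / denominator)
}

# E[MI] under the permutation (hypergeometric) null for fixed marginals.
expected_mutual_information <- function(ai, bj, n) {
  emi <- 0
  lg <- lgamma
  for (i in seq_along(ai)) {
    for (j in seq_along(bj)) {
      a <- ai[i]
      b <- bj[j]
      lo <- max(1, a + b - n)
      hi <- min(a, b)
      if (hi < lo) next
      for (nij in lo:hi) {
        logp <- lg(a + 1) + lg(b + 1) + lg(n - a + 1) + lg(n - b + 1) -
          lg(n + 1) - lg(nij + 1) - lg(a - nij + 1) - lg(b - nij + 1) -
          lg(n - a - b + nij + 1)
        emi <- emi + exp(logp) * (nij / n) * log(n * nij / (a * b))
      }
    }
  }
  emi
}

check_label_args <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop(sprintf("label vectors differ in length (%d vs %d)",
                 length(labels_a), length(labels_b)))
  }
  if (length(labels_a) < 2L) stop("need at least 2 samples")
  invisible(TRUE)
}
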