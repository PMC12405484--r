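# Internal helpers shared across modules.

# Deterministic child seeds: keep every derived seed a valid 32-bit integer.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1013L * as.integer(offset)) %% 214748329L
}

# Moore-Penrose pseudoinverse solve for possibly rank-deficient least squares.
# Returns the minimum-norm coefficient vector/matrix.
pinv_solve <- function(X, y, tol = 1e-10) {
  sv <- svd(X)
  keep <- sv$d > tol * max(sv$d, 0)
  if (!any(keep)) {
    return(matrix(0, ncol(X), NCOL(y)))
  }
  dinv <- ifelse(keep, 1 / sv$d, 0)
  sv$v %*% (dinv * crossprod(sv$u, as.matrix(y)))
}

# log-determinant of a symmetric PSD matrix via Cholesky, with a small ridge
# fallback when the block is numerically singular.
logdet_psd <- function(S, ridge = 1e-8) {
  if (length(S) == 0L) return(0)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- chol(S + diag(ridge, nrow(S)))
  }
  2 * sum(log(diag(ch)))
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}
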