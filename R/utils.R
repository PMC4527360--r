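# internal numerical helpers

# Moore-Penrose pseudo-inverse of a symmetric PSD matrix (e.g. crossprod(A0)),
# singular values below rcond * largest dropped. Used for the constraint
# projector, where the dummy-coded nuisance block is rank-deficient by design.
.pinvSym <- function(M, rcond = 1e-12) {
  s <- svd(M)
  keep <- s$d > rcond * max(s$d, 0)
  if (!any(keep)) return(matrix(0, nrow(M), ncol(M)))
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

# Orthonormal basis of the column space of A (columns), tolerance relative to
# the largest singular value.
.colBasis <- function(A, rcond = 1e-8) {
  if (is.null(A) || ncol(A) == 0L) return(matrix(0, nrow(A %||% matrix(0, 1, 0)), 0))
  s <- svd(A, nu = min(dim(A)), nv = 0)
  keep <- s$d > rcond * max(s$d, 0)
  s$u[, keep, drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.matrixRank <- function(A, rcond = 1e-10) {
  if (length(A) == 0L) return(0L)
  d <- svd(A, nu = 0, nv = 0)$d
  sum(d > rcond * max(d, 0))
}

# run expr under a seed without disturbing the caller's RNG stream;
# seed = NULL means "use the current stream"
.withSeed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

.checkMatrix <- function(X, what = "X") {
  if (!is.matrix(X) || !is.numeric(X))
    stop(sprintf("'%s' must be a numeric matrix", what), call. = FALSE)
  if (anyNA(X)) stop(sprintf("'%s' contains missing values", what), call. = FALSE)
  X
}

# center the columns of the dummy response
.centerCols <- function(M) {
  mu <- colMeans(M)
  list(centered = sweep(M, 2L, mu, "-"), means = mu)
}
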