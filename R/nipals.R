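# Shared NIPALS PLS2 engine. The constrained variant (oCPLS2-DA) differs only
# by a projection applied to the weight vector at every iteration, so all
# discriminant fits run through this single code path.
#
# X: centered sample x feature matrix; Yc: centered dummy response; Z: NULL
# or centered constraint block. Returns W, P, C, T, r2x, r2yCum.
.nipalsPLS2 <- function(X, Yc, A, Z = NULL, tol = 1e-10, maxIter = 500L) {
  n <- nrow(X); p <- ncol(X); N <- ncol(Yc)
  if (A < 1L) stop("'A' must be at least 1")
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  C <- matrix(0, N, A); Tm <- matrix(0, n, A)
  r2x <- numeric(A); r2yCum <- numeric(A)
  ssx0 <- sum(X^2); ssy0 <- sum(Yc^2)
  if (ssx0 == 0) stop("X has no variance")
  Xc <- X; Yd <- Yc
  useZ <- !is.null(Z) && ncol(Z) > 0L
  for (a in seq_len(A)) {
    if (sum(Xc^2) < 1e-12 * ssx0)
      stop(sprintf("component %d exceeds the rank of X", a))
    U <- NULL
    if (useZ) {
      # null-space projector of the forbidden span: A0 = Xc' Z, recomputed
      # from the deflated X so the constraint is exact for every component
      A0 <- crossprod(Xc, Z)
      U <- .colBasis(A0, rcond = 1e-6)   # = sqrt(1e-12) cutoff on A0'A0
    }
    # start the iteration at its fixed point: the NIPALS weight of a PLS2
    # component is the dominant left singular vector of (projected) Xc'Yd,
    # so seeding u with the matching right singular pair makes the loop a
    # verification pass in the regular case and a genuine power iteration
    # only near eigenvalue ties
    M <- crossprod(Xc, Yd)
    if (!is.null(U) && ncol(U)) M <- M - U %*% crossprod(U, M)
    u <- if (max(abs(M)) > 0) Yd %*% svd(M, nu = 0, nv = 1L)$v
         else Yd[, which.max(colSums(Yd^2)), drop = FALSE]
    if (sum(u^2) < .Machine$double.eps)
      u <- Yd[, which.max(colSums(Yd^2)), drop = FALSE]
    tOld <- rep(0, n)
    tvec <- NULL
    converged <- FALSE
    for (it in seq_len(maxIter)) {
      w <- crossprod(Xc, u) / sum(u^2)
      wNorm0 <- sqrt(sum(w^2))
      if (!is.null(U) && ncol(U)) w <- w - U %*% crossprod(U, w)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-8 * max(wNorm0, .Machine$double.eps))
        stop(sprintf(
          "class structure confounded with constraint at component %d", a))
      w <- w / nw
      tvec <- Xc %*% w
      if (sum(tvec^2) < 1e-12 * ssx0 / n)
        stop(sprintf("component %d exceeds the rank of X", a))
      cvec <- crossprod(Yd, tvec) / sum(tvec^2)
      u <- Yd %*% cvec / sum(cvec^2)
      if (sqrt(sum((tvec - tOld)^2)) <= tol * sqrt(sum(tvec^2))) {
        converged <- TRUE
        break
      }
      tOld <- tvec
    }
    if (!converged)
      stop(sprintf("NIPALS did not converge at component %d", a))
    # sign convention: largest-magnitude weight entry positive
    j <- which.max(abs(w))
    if (w[j] < 0) { w <- -w; tvec <- -tvec; cvec <- -cvec }
    pvec <- crossprod(Xc, tvec) / sum(tvec^2)
    Xc <- Xc - tcrossprod(tvec, pvec)
    Yd <- Yd - tcrossprod(tvec, cvec)
    W[, a] <- w; P[, a] <- pvec; C[, a] <- cvec; Tm[, a] <- tvec
    r2x[a] <- sum(tvec^2) * sum(pvec^2) / ssx0
    r2yCum[a] <- if (ssy0 > 0) 1 - sum(Yd^2) / ssy0 else NA_real_
  }
  rownames(W) <- rownames(P) <- colnames(X)
  rownames(Tm) <- rownames(X)
  rownames(C) <- colnames(Yc)
  list(W = W, P = P, C = C, T = Tm, r2x = r2x, r2yCum = r2yCum)
}
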