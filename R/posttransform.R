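#' Post-transformation: rotate a PLS model into predictive and Y-orthogonal
#' blocks
#'
#' A fitted PLS2-DA or oCPLS2-DA model with A components usually spreads the
#' class-discriminating variation over all components. The post-transformation
#' rotates the weight matrix by an orthogonal G built from the singular value
#' decomposition of M = Yc'T: the right singular vectors with nonzero
#' singular value span the predictive block (at most N - 1 directions for N
#' classes, ordered by decreasing singular value), and an orthonormal basis
#' of the null space of M spans the response-orthogonal block (ordered by
#' decreasing score variance). Scores, weights and Y-loadings rotate by the
#' same G, and because G is orthogonal the regression coefficients — hence
#' all fitted and predicted responses — are unchanged.
#'
#' @param model a fitted \linkS4class{PLSDAModel} or subclass
#' @param Y the \linkS4class{ClassResponse} used in fitting (or the label
#'   vector); its class order must match the model's
#' @return a \linkS4class{PostTransformedModel}
#' @section Degenerate cases: when A <= rank(Yc'T) there is nothing to
#'   split; the rotation is the identity on the predictive block, the
#'   orthogonal block is empty, and a warning is emitted.
#' @export
postTransform <- function(model, Y) {
  if (!is(model, "PLSDAModel")) stop("post-transformation needs a fitted PLS-DA model")
  if (!is(Y, "ClassResponse")) Y <- dummyCode(Y)
  if (!identical(Y@classes, model@classes))
    stop("Y does not match the classes the model was fitted with")
  Yc <- .centerCols(Y@Y)$centered
  Tm <- model@T
  A <- model@A
  M <- crossprod(Yc, Tm)                      # N x A
  s <- svd(M, nu = 0, nv = A)                 # V is A x A
  r <- sum(s$d > 1e-10 * max(s$d, 0))
  nPred <- min(A, r)
  if (nPred == A)
    warning("A <= rank(Yc'T): no response-orthogonal components to split off")
  Gpred <- s$v[, seq_len(nPred), drop = FALSE]
  Gorth <- s$v[, setdiff(seq_len(A), seq_len(nPred)), drop = FALSE]
  if (ncol(Gorth)) {
    # order orthogonal components by decreasing score variance
    v <- colSums((Tm %*% Gorth)^2)
    Gorth <- Gorth[, order(v, decreasing = TRUE), drop = FALSE]
  }
  G <- cbind(Gpred, Gorth)
  new("PostTransformedModel", base = model, G = G,
      nPredictive = as.integer(nPred),
      Tpred = Tm %*% Gpred, Torth = Tm %*% Gorth,
      Wpred = model@W %*% Gpred, Worth = model@W %*% Gorth,
      Cpred = model@C %*% Gpred)
}

#' @describeIn postTransform predictions through the rotated model; equal to
#'   predictions of the base model within numerical precision
#' @param object a \linkS4class{PostTransformedModel}
#' @param newdata sample x feature matrix on the model's scale
#' @param ... unused
#' @export
setMethod("predict", "PostTransformedModel", function(object, newdata, ...) {
  base <- object@base
  G <- object@G
  # rotate W, P, C by the orthogonal G; B is invariant, computed here from
  # the rotated blocks so the rotated model is exercised end to end
  W <- base@W %*% G; P <- base@P %*% G; C <- base@C %*% G
  if (is(newdata, "FeatureTable")) newdata <- intensities(newdata)
  if (is(base, "OPLSDAModel")) {
    for (j in seq_len(ncol(base@Wo))) {
      to <- newdata %*% base@Wo[, j]
      newdata <- newdata - tcrossprod(to, base@Po[, j])
    }
  }
  Yhat <- newdata %*% (W %*% solve(crossprod(P, W), t(C)))
  Yhat <- sweep(Yhat, 2L, base@yMeans, "+")
  colnames(Yhat) <- base@classes
  Yhat
})
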