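#' Principal component analysis
#'
#' Exploratory PCA of a centered (or autoscaled) matrix via the singular value
#' decomposition; successive components maximise explained variance and
#' scores are orthogonal. The sign of each component is fixed so the
#' largest-magnitude loading entry is positive.
#'
#' @param X centered sample x feature matrix (or a centered/autoscaled
#'   \linkS4class{FeatureTable})
#' @param A number of components, at most the rank of X
#' @return a \linkS4class{PCAModel}; \code{explainedVariance} gives the
#'   fraction of total variance per component
#' @export
fitPCA <- function(X, A) {
  if (is(X, "FeatureTable")) X <- intensities(X)
  X <- .checkMatrix(X)
  s <- svd(X)
  rank <- sum(s$d > max(dim(X)) * .Machine$double.eps * max(s$d, 0))
  if (A > rank)
    stop(sprintf("A = %d exceeds rank(X) = %d", A, rank))
  idx <- seq_len(A)
  P <- s$v[, idx, drop = FALSE]
  Tm <- s$u[, idx, drop = FALSE] %*% diag(s$d[idx], A, A)
  flip <- vapply(idx, function(a) {
    j <- which.max(abs(P[, a])); sign(P[j, a])
  }, numeric(1))
  P <- sweep(P, 2L, flip, "*")
  Tm <- sweep(Tm, 2L, flip, "*")
  rownames(P) <- colnames(X); rownames(Tm) <- rownames(X)
  new("PCAModel", kind = "pca", A = as.integer(A), T = Tm, P = P, W = P,
      center = numeric(0), scale = numeric(0),
      r2x = s$d[idx]^2 / sum(s$d^2))
}

#' PLS2 discriminant analysis (NIPALS)
#'
#' Fits a PLS2 model on a centered X block against the dummy-coded class
#' response (centered internally). Per component, NIPALS iterates
#' u -> w = X'u/(u'u) -> normalise -> t = Xw -> c = Y't/(t't) -> u = Yc/(c'c)
#' until the score stabilises (relative change < 1e-10, at most 500
#' iterations), then deflates X by t p' and Y by t c'.
#'
#' @param X centered sample x feature matrix (or centered
#'   \linkS4class{FeatureTable})
#' @param Y a \linkS4class{ClassResponse} (or a vector of class labels)
#' @param A number of latent components
#' @return a \linkS4class{PLSDAModel}
#' @seealso [fitOCPLSDA()] for the vintage-constrained variant,
#'   [postTransform()] for the predictive/orthogonal rotation
#' @export
fitPLSDA <- function(X, Y, A) {
  if (is(X, "FeatureTable")) X <- intensities(X)
  X <- .checkMatrix(X)
  if (!is(Y, "ClassResponse")) Y <- dummyCode(Y)
  yc <- .centerCols(Y@Y)
  fit <- .nipalsPLS2(X, yc$centered, A)
  new(Class = "PLSDAModel", kind = "pls2da", A = as.integer(A),
      T = fit$T, P = fit$P, W = fit$W, C = fit$C,
      classes = Y@classes, yMeans = yc$means,
      center = numeric(0), scale = numeric(0),
      r2x = fit$r2x, r2yCum = fit$r2yCum)
}

# regression coefficients B = W (P'W)^-1 C'
.plsBeta <- function(object) {
  object@W %*% solve(crossprod(object@P, object@W), t(object@C))
}

#' Predict the class response for new samples
#'
#' \code{Yhat = X_new W (P'W)^-1 C'} plus the training Y means. New samples
#' must be preprocessed (centered/scaled) with the training parameters.
#'
#' @param object a fitted \linkS4class{PLSDAModel} (or subclass)
#' @param newdata sample x feature matrix on the model's scale
#' @return sample x class matrix of predicted responses
#' @export
setMethod("predict", "PLSDAModel", function(object, newdata, ...) {
  if (is(newdata, "FeatureTable")) newdata <- intensities(newdata)
  if (ncol(newdata) != nrow(object@W))
    stop(sprintf("newdata has %d features but the model expects %d",
                 ncol(newdata), nrow(object@W)))
  Yhat <- newdata %*% .plsBeta(object)
  Yhat <- sweep(Yhat, 2L, object@yMeans, "+")
  colnames(Yhat) <- object@classes
  Yhat
})

#' @describeIn classify predicted class = column with the maximal predicted
#'   response; ties broken by class order
#' @export
setMethod("classify", "PLSDAModel", function(object, newdata, ...) {
  Yhat <- predict(object, newdata)
  classifyResponses(Yhat, object@classes)
})

#' Turn predicted responses into class labels
#'
#' @param Yhat sample x class matrix of predicted responses
#' @param classes class labels for the columns (defaults to colnames)
#' @return character vector; per row the class of the maximal entry, ties
#'   broken in favour of the earlier class
#' @export
classifyResponses <- function(Yhat, classes = colnames(Yhat)) {
  if (is.null(classes) || ncol(Yhat) < 2L)
    stop("'Yhat' needs >= 2 named class columns")
  classes[apply(Yhat, 1L, which.max)]
}
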