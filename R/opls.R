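#' OPLS-DA: orthogonal-filtered PLS discriminant analysis
#'
#' Splits X variation into components predictive of the class response and
#' components orthogonal to it. Per orthogonal component: a one-component
#' PLS2 fit on the current X gives the predictive weight w and the loading p
#' of its provisional score; the orthogonal weight is p with its projection
#' onto the span of X'Yc removed, normalised; t_o = X w_o and X is deflated
#' by t_o p_o'. Because w_o is orthogonal to every column of X'Yc, the
#' orthogonal scores satisfy Yc'T_o = 0 exactly. After filtering,
#' min(N - 1, remaining rank) predictive components are fitted on the
#' filtered X.
#'
#' @param X centered sample x feature matrix (or centered
#'   \linkS4class{FeatureTable})
#' @param Y a \linkS4class{ClassResponse} or vector of class labels
#' @param nOrth number of Y-orthogonal components to strip
#' @return an \linkS4class{OPLSDAModel}; \code{orthScores} returns T_o
#' @export
fitOPLSDA <- function(X, Y, nOrth = 0L) {
  if (is(X, "FeatureTable")) X <- intensities(X)
  X <- .checkMatrix(X)
  if (!is(Y, "ClassResponse")) Y <- dummyCode(Y)
  yc <- .centerCols(Y@Y)
  Yc <- yc$centered
  N <- length(Y@classes)
  nPred <- N - 1L
  rk <- .matrixRank(X)
  if (nOrth > rk - nPred)
    stop(sprintf("nOrth = %d exceeds rank(X) - (N-1) = %d", nOrth, rk - nPred))
  p <- ncol(X)
  Wo <- matrix(0, p, nOrth); Po <- matrix(0, p, nOrth)
  To <- matrix(0, nrow(X), nOrth)
  Xf <- X
  for (j in seq_len(nOrth)) {
    V <- .colBasis(crossprod(Xf, Yc))       # basis of the predictive span
    one <- .nipalsPLS2(Xf, Yc, 1L)
    w <- one$W[, 1L]; tvec <- one$T[, 1L]
    pvec <- crossprod(Xf, tvec)[, 1L] / sum(tvec^2)
    wo <- pvec - V %*% crossprod(V, pvec)
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-10 * sqrt(sum(pvec^2)))
      stop(sprintf("no Y-orthogonal variation left at component %d", j))
    wo <- wo / nwo
    to <- Xf %*% wo
    po <- crossprod(Xf, to) / sum(to^2)
    Xf <- Xf - tcrossprod(to, po)
    Wo[, j] <- wo; Po[, j] <- po; To[, j] <- to
  }
  fit <- .nipalsPLS2(Xf, Yc, nPred)
  rownames(Wo) <- rownames(Po) <- colnames(X)
  rownames(To) <- rownames(X)
  new(Class = "OPLSDAModel", kind = "oplsda", A = as.integer(nPred),
      T = fit$T, P = fit$P, W = fit$W, C = fit$C,
      classes = Y@classes, yMeans = yc$means,
      center = numeric(0), scale = numeric(0),
      r2x = fit$r2x, r2yCum = fit$r2yCum,
      Wo = Wo, Po = Po, To = To)
}

#' @describeIn fitOPLSDA prediction first strips the orthogonal components
#'   from the new data (sequentially, with the training orthogonal
#'   weights/loadings), then applies the predictive model
#' @param object a fitted \linkS4class{OPLSDAModel}
#' @param newdata sample x feature matrix on the model's scale
#' @param ... unused
#' @export
setMethod("predict", "OPLSDAModel", function(object, newdata, ...) {
  if (is(newdata, "FeatureTable")) newdata <- intensities(newdata)
  if (ncol(newdata) != nrow(object@W))
    stop(sprintf("newdata has %d features but the model expects %d",
                 ncol(newdata), nrow(object@W)))
  for (j in seq_len(ncol(object@Wo))) {
    to <- newdata %*% object@Wo[, j]
    newdata <- newdata - tcrossprod(to, object@Po[, j])
  }
  callNextMethod(object, newdata)
})

#' Battery of OPLS-DA models for terroir-feature classifications
#'
#' Fits and validates one OPLS-DA model per candidate classification of the
#' samples (e.g. soil pH below/above a threshold, altitude bands), mirroring
#' a model-screening table: each row reports the 7-fold Q2 and the
#' permutation p-value, and a model is flagged reliable only when
#' Q2 > 0.5 and the permutation test passes.
#'
#' @param X sample x feature matrix on the raw scale expected by
#'   \code{recipe} (or a \linkS4class{FeatureTable})
#' @param classifications named list; each element is a per-sample vector of
#'   class labels
#' @param recipe a [modelRecipe()] with \code{method = "oplsda"}; its
#'   preprocessing is re-estimated inside each cross-validation fold
#' @param maxOrth orthogonal-component counts 0..maxOrth are screened and the
#'   first local maximum of Q2 is kept
#' @param nFolds folds for Q2 (default 7)
#' @param nPerm permutations for the response permutation test
#' @param q2Threshold reliability cutoff on Q2 (default 0.5)
#' @param seed seed for folds and permutations
#' @return data.frame with one row per classification: name, classes, nOrth,
#'   q2, permutation p, estimable and reliable flags
#' @export
featureModelBattery <- function(X, classifications,
                                recipe = modelRecipe(method = "oplsda",
                                                     scaling = "center"),
                                maxOrth = 3L, nFolds = 7L, nPerm = 199L,
                                q2Threshold = 0.5, seed = NULL) {
  if (is(X, "FeatureTable")) X <- intensities(X)
  stopifnot(recipe@method == "oplsda")
  rows <- lapply(names(classifications), function(nm) {
    labels <- as.character(classifications[[nm]])
    counts <- table(labels)
    if (length(counts) < 2L || any(counts == 0L))
      return(data.frame(name = nm, classes = paste(names(counts),
                                                   collapse = "|"),
                        nOrth = NA_integer_, q2 = NA_real_, pValue = NA_real_,
                        estimable = FALSE, reliable = FALSE))
    res <- tryCatch({
      q2s <- vapply(0:maxOrth, function(k)
        crossvalQ2(recipe, X, labels, A = k, nFolds = nFolds, seed = seed),
        numeric(1))
      kSel <- .firstMaximum(q2s) - 1L   # grid starts at nOrth = 0
      perm <- permutationTest(recipe, X, labels, A = kSel, nPerm = nPerm,
                              nFolds = nFolds, seed = seed)
      data.frame(name = nm, classes = paste(names(counts), collapse = "|"),
                 nOrth = kSel, q2 = q2s[kSel + 1L], pValue = perm$pValue,
                 estimable = TRUE,
                 reliable = q2s[kSel + 1L] > q2Threshold && perm$passed)
    }, error = function(e)
      data.frame(name = nm, classes = paste(names(counts), collapse = "|"),
                 nOrth = NA_integer_, q2 = NA_real_, pValue = NA_real_,
                 estimable = FALSE, reliable = FALSE))
    res
  })
  do.call(rbind, rows)
}
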