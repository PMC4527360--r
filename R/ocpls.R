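#' Orthogonal constrained PLS2-DA
#'
#' PLS2-DA whose latent components are constrained orthogonal to a nuisance
#' block Z (typically the centered dummy codes of the vintage). The
#' constraint acts inside the NIPALS weight-maximisation step: after every
#' weight update, w is projected onto the null space of A0 = X'Z (with X the
#' deflated block of the current component, so the constraint is exact for
#' every component) and renormalised. Consequently every score column
#' satisfies t'Z = 0, and no information correlated with the nuisance factor
#' can enter the latent space.
#'
#' With an empty constraint (\code{Z = NULL} or zero columns) the algorithm
#' path is identical to [fitPLSDA()].
#'
#' @param X centered sample x feature matrix (or centered
#'   \linkS4class{FeatureTable})
#' @param Y a \linkS4class{ClassResponse} or vector of class labels
#' @param Z a \linkS4class{ConstraintBlock}, a centered matrix, a vector of
#'   nuisance labels, or \code{NULL} for no constraint
#' @param A number of latent components
#' @return an \linkS4class{OCPLSDAModel}
#' @section Errors: if the class direction lies entirely inside the span of
#'   the constraint (the projected weight vanishes), the fit aborts with a
#'   "class structure confounded with constraint" error.
#' @export
fitOCPLSDA <- function(X, Y, Z, A) {
  if (is(X, "FeatureTable")) X <- intensities(X)
  X <- .checkMatrix(X)
  if (!is(Y, "ClassResponse")) Y <- dummyCode(Y)
  cf <- NA_character_
  if (is(Z, "ConstraintBlock")) {
    cf <- Z@sourceFactor
    Z <- Z@Z
  } else if (!is.null(Z) && !is.matrix(Z)) {
    Z <- buildConstraintBlock(Z)@Z
  }
  if (is.null(Z)) Z <- matrix(0, nrow(X), 0L)
  if (nrow(Z) != nrow(X)) stop("Z and X must have the same rows")
  yc <- .centerCols(Y@Y)
  fit <- .nipalsPLS2(X, yc$centered, A, Z = Z)
  new(Class = "OCPLSDAModel", kind = "ocpls2da", A = as.integer(A),
      T = fit$T, P = fit$P, W = fit$W, C = fit$C,
      classes = Y@classes, yMeans = yc$means,
      center = numeric(0), scale = numeric(0),
      r2x = fit$r2x, r2yCum = fit$r2yCum,
      Z = Z, constraintFactor = cf)
}

#' Quantify score-level constraint orthogonality
#'
#' @param model a fitted model
#' @param Z constraint matrix (defaults to the model's own block)
#' @return the maximum absolute cosine between any score column and any
#'   constraint column; ~0 for a valid oCPLS2-DA fit
#' @export
constraintOrthogonality <- function(model, Z = NULL) {
  if (is.null(Z)) {
    if (!is(model, "OCPLSDAModel")) stop("no constraint block available")
    Z <- model@Z
  }
  if (is(Z, "ConstraintBlock")) Z <- Z@Z
  Tm <- scores(model)
  num <- abs(crossprod(Tm, Z))
  den <- outer(sqrt(colSums(Tm^2)), sqrt(colSums(Z^2)))
  den[den == 0] <- 1
  max(num / den)
}

# R2 of each column of Z regressed on the score matrix (ordinary least
# squares); measures how much nuisance information the latent space carries
.scoreOnZR2 <- function(Tm, Z) {
  apply(Z, 2L, function(z) {
    zc <- z - mean(z)
    tss <- sum(zc^2)
    if (tss == 0) return(NA_real_)
    fit <- lm.fit(cbind(1, Tm), z)
    1 - sum(fit$residuals^2) / tss
  })
}

#' Compare unconstrained and constrained fits on the same data
#'
#' Fits plain PLS2-DA and (if a constraint is given) oCPLS2-DA, and reports
#' for each arm how much nuisance information the scores carry (R2 of every
#' constraint column regressed on the scores) and the cross-validated class
#' accuracy. When the nuisance effect dominates, the unconstrained scores
#' predict the nuisance factor well while the constrained scores carry none
#' of it.
#'
#' @param X centered sample x feature matrix
#' @param labels per-sample class labels
#' @param constraintLabels per-sample nuisance labels, or \code{NULL} to skip
#'   the constrained arm
#' @param A number of latent components
#' @param nFolds folds for the accuracy cross-validation
#' @param seed optional seed for the fold shuffle
#' @return list with elements \code{plsda} and (optionally) \code{ocplsda},
#'   each containing \code{zR2} and \code{cvAccuracy}
#' @export
compareConfounding <- function(X, labels, constraintLabels = NULL, A,
                               nFolds = 7L, seed = NULL) {
  if (is(X, "FeatureTable")) X <- intensities(X)
  Z <- if (!is.null(constraintLabels))
    buildConstraintBlock(constraintLabels)@Z else NULL
  arm <- function(method) {
    recipe <- modelRecipe(method = method, scaling = "none",
                          constraintLabels = constraintLabels)
    model <- if (method == "ocplsda")
      fitOCPLSDA(X, labels, Z, A) else fitPLSDA(X, labels, A)
    list(
      zR2 = if (!is.null(Z)) .scoreOnZR2(scores(model), Z) else NULL,
      cvAccuracy = cvAccuracy(recipe, X, labels, A, nFolds = nFolds,
                              seed = seed))
  }
  out <- list(plsda = arm("plsda"))
  if (!is.null(Z)) out$ocplsda <- arm("ocplsda")
  out
}

#' Project out all nuisance-correlated variance from X
#'
#' Utility alternative to the weight-step constraint: replaces X by
#' \code{X - Z pinv(Z'Z) Z' X}, removing every direction of sample space
#' correlated with the nuisance block before an ordinary PLS-DA fit. This is
#' a different estimator from [fitOCPLSDA()] (it also strips
#' nuisance-correlated variance from the loadings) and is provided for
#' comparison only.
#'
#' @param X centered sample x feature matrix
#' @param Z constraint block (matrix, \linkS4class{ConstraintBlock} or
#'   labels)
#' @return the deflated matrix
#' @export
projectOutConstraint <- function(X, Z) {
  if (is(X, "FeatureTable")) X <- intensities(X)
  if (is(Z, "ConstraintBlock")) Z <- Z@Z
  if (!is.matrix(Z)) Z <- buildConstraintBlock(Z)@Z
  X - Z %*% (.pinvSym(crossprod(Z)) %*% crossprod(Z, X))
}
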