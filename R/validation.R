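#' ModelRecipe: preprocessing + model specification for cross-validation
#'
#' Bundles everything a cross-validation fold must re-estimate from its
#' training rows: the preprocessing chain (median fold change normalization,
#' log transform, centering or autoscaling) and the model family, including
#' the nuisance labels from which the constraint block is rebuilt on the
#' training subset.
#'
#' @slot method "plsda", "ocplsda" or "oplsda"
#' @slot scaling "center", "autoscale" or "none"
#' @slot mfc apply median fold change normalization inside each fold
#' @slot log apply ln(x + epsilon) inside each fold
#' @slot epsilon offset for the log transform
#' @slot constraintLabels per-sample nuisance labels (oCPLS2-DA) or NULL
#' @exportClass ModelRecipe
setClass("ModelRecipe",
  representation(method = "character", scaling = "character",
                 mfc = "logical", log = "logical", epsilon = "numeric",
                 constraintLabels = "ANY"))

#' @rdname ModelRecipe-class
#' @param method model family
#' @param scaling per-fold scaling of X
#' @param mfc,log,epsilon per-fold preprocessing before scaling
#' @param constraintLabels nuisance labels for \code{method = "ocplsda"}
#' @return a \code{ModelRecipe}
#' @export
modelRecipe <- function(method = c("plsda", "ocplsda", "oplsda"),
                        scaling = c("center", "autoscale", "none"),
                        mfc = FALSE, log = FALSE, epsilon = 1,
                        constraintLabels = NULL) {
  method <- match.arg(method)
  if (method == "ocplsda" && is.null(constraintLabels))
    stop("'ocplsda' needs constraintLabels")
  new("ModelRecipe", method = method, scaling = match.arg(scaling),
      mfc = mfc, log = log, epsilon = epsilon,
      constraintLabels = constraintLabels)
}

# fit the recipe's model on a preprocessed training block
.recipeFit <- function(recipe, Xtr, Ytr, A, trainIdx) {
  switch(recipe@method,
    plsda = fitPLSDA(Xtr, Ytr, A),
    ocplsda = {
      zl <- as.character(recipe@constraintLabels)[trainIdx]
      fitOCPLSDA(Xtr, Ytr, buildConstraintBlock(zl)@Z, A)
    },
    oplsda = fitOPLSDA(Xtr, Ytr, nOrth = A))
}

#' Deterministic stratified fold assignment
#'
#' Samples are sorted by (class, stable index) and dealt round-robin into the
#' folds (venetian blinds), so every sample is held out exactly once and each
#' fold keeps the class proportions. With a seed, the order within each class
#' is shuffled first; without one the assignment is fully deterministic.
#'
#' @param labels per-sample class labels
#' @param nFolds number of folds (>= 2)
#' @param seed optional shuffle seed
#' @return integer vector of fold ids in 1..nFolds, one per sample
#' @export
cvFolds <- function(labels, nFolds, seed = NULL) {
  if (nFolds < 2L) stop("'nFolds' must be at least 2")
  labels <- as.character(labels)
  n <- length(labels)
  ord <- .withSeed(seed, {
    idx <- seq_len(n)
    if (!is.null(seed))
      idx <- unlist(lapply(split(idx, labels), sample), use.names = FALSE)
    idx[order(labels[idx])]
  })
  folds <- integer(n)
  folds[ord] <- rep_len(seq_len(nFolds), n)
  folds
}

# One full-CV pass: each sample held out exactly once. Preprocessing and the
# constraint block are re-estimated on the training rows of every fold; the
# held-out rows are transformed with the training parameters. Returns PRESS
# and SS terms (training-fold Y centering) and the held-out class labels.
.cvRun <- function(recipe, X, labels, A, nFolds, seed = NULL) {
  if (is(X, "FeatureTable")) X <- intensities(X)
  labels <- as.character(labels)
  classes <- unique(labels)
  folds <- cvFolds(labels, nFolds, seed)
  press <- 0; ss <- 0
  predLabels <- character(length(labels))
  for (k in seq_len(nFolds)) {
    te <- which(folds == k); tr <- which(folds != k)
    lost <- setdiff(classes, labels[tr])
    if (length(lost))
      stop("fold ", k, " removes all samples of class '", lost[1L],
           "'; use stratified folds or fewer folds")
    prep <- .estimatePreprocess(X[tr, , drop = FALSE], recipe)
    Xte <- .applyPreprocess(X[te, , drop = FALSE], recipe, prep$params)
    Ytr <- dummyCode(factor(labels[tr], levels = classes))
    model <- .recipeFit(recipe, prep$X, Ytr, A, tr)
    Yhat <- predict(model, Xte)                       # includes training means
    Yte <- dummyCode(factor(labels[te], levels = classes))@Y
    muTr <- colMeans(Ytr@Y)
    press <- press + sum((Yte - Yhat)^2)
    ss <- ss + sum(sweep(Yte, 2L, muTr, "-")^2)
    predLabels[te] <- classifyResponses(Yhat, classes)
  }
  list(press = press, ss = ss, q2 = 1 - press / ss,
       accuracy = mean(predLabels == labels), predLabels = predLabels)
}

#' Cross-validated Q2
#'
#' N-fold full cross-validation: every sample is held out exactly once, and
#' Q2 = 1 - PRESS/SS with both PRESS and SS accumulated over held-out samples
#' under training-fold preprocessing and Y centering.
#'
#' @param recipe a [modelRecipe()]
#' @param X sample x feature matrix on the scale the recipe expects (raw when
#'   the recipe normalises, already-preprocessed with
#'   \code{scaling = "none"})
#' @param labels per-sample class labels
#' @param A model size: latent components for plsda/ocplsda, orthogonal
#'   components for oplsda (predictive components are fixed at N - 1)
#' @param nFolds number of folds (the protocol uses 6, 7 and 8)
#' @param seed optional fold-shuffle seed
#' @return Q2 (at most 1; negative when the model predicts worse than the
#'   class means)
#' @export
crossvalQ2 <- function(recipe, X, labels, A, nFolds = 7L, seed = NULL) {
  .cvRun(recipe, X, labels, A, nFolds, seed)$q2
}

#' Cross-validated classification accuracy
#'
#' @inheritParams crossvalQ2
#' @return fraction of held-out samples assigned to their true class
#' @export
cvAccuracy <- function(recipe, X, labels, A, nFolds = 7L, seed = NULL) {
  .cvRun(recipe, X, labels, A, nFolds, seed)$accuracy
}

#' Permutation test on the class response
#'
#' The class labels are permuted \code{nPerm} times; the 7-fold (by default)
#' Q2 is recomputed for each permutation, and the p-value uses the add-one
#' estimator p = (1 + #\{Q2_perm >= Q2_obs\}) / (nPerm + 1), so p is never
#' zero. The test passes when p < alpha.
#'
#' @inheritParams crossvalQ2
#' @param nPerm number of permutations (>= 1); the protocol default is 400
#' @param alpha significance level (default 0.05)
#' @return list with observedQ2, nullQ2 (length nPerm), pValue, passed, nPerm
#' @export
permutationTest <- function(recipe, X, labels, A, nPerm = 400L, nFolds = 7L,
                            alpha = 0.05, seed = NULL) {
  nPerm <- as.integer(nPerm)
  if (nPerm < 1L) stop("'nPerm' must be at least 1")
  if (is(X, "FeatureTable")) X <- intensities(X)
  labels <- as.character(labels)
  observed <- crossvalQ2(recipe, X, labels, A, nFolds, seed)
  # constraint labels stay attached to the samples; only the class labels
  # are permuted
  nullQ2 <- .withSeed(seed, vapply(seq_len(nPerm), function(b) {
    crossvalQ2(recipe, X, sample(labels), A, nFolds, seed = NULL)
  }, numeric(1)))
  p <- (1 + sum(nullQ2 >= observed)) / (nPerm + 1)
  list(observedQ2 = observed, nullQ2 = nullQ2, pValue = p,
       passed = p < alpha, nPerm = nPerm)
}

# first local maximum of a Q2 sequence over A = 1..length(q2):
# smallest a with q2[a] >= q2[a+1]; strictly increasing -> last index
.firstMaximum <- function(q2) {
  if (length(q2) == 1L) return(1L)
  for (a in seq_len(length(q2) - 1L))
    if (q2[a] >= q2[a + 1L]) return(a)
  length(q2)
}

#' Select the number of latent components
#'
#' Computes Q2 (7-fold by default) for A = 1..maxA and selects the first
#' local maximum, under the constraint that the selected model passes the
#' permutation test; if it fails, later local maxima are tried in turn, and
#' if none passes the model is rejected. A strictly increasing Q2 sequence
#' selects maxA with a warning.
#'
#' @inheritParams permutationTest
#' @param maxA largest component count to consider
#' @return a \linkS4class{ValidationReport} with slots selectedA, status
#'   ("accepted"/"rejected"), the Q2 sequence (in
#'   \code{permutation$q2Sequence}) and the permutation record of the
#'   selected A
#' @export
selectComponents <- function(recipe, X, labels, maxA, nFolds = 7L,
                             nPerm = 400L, alpha = 0.05, seed = NULL) {
  if (is(X, "FeatureTable")) X <- intensities(X)
  q2s <- vapply(seq_len(maxA), function(a)
    crossvalQ2(recipe, X, labels, a, nFolds, seed), numeric(1))
  if (maxA > 1L && all(diff(q2s) > 0))
    warning("Q2 still increasing at maxA; consider a larger maxA")
  # candidate local maxima in order
  cand <- integer(0)
  a <- 1L
  q2pad <- c(q2s, -Inf)
  for (a in seq_len(maxA)) if (q2pad[a] >= q2pad[a + 1L]) cand <- c(cand, a)
  perm <- NULL; sel <- NA_integer_; status <- "rejected"
  for (a in cand) {
    perm <- permutationTest(recipe, X, labels, a, nPerm, nFolds, alpha, seed)
    if (perm$passed) { sel <- a; status <- "accepted"; break }
  }
  permRec <- if (is.null(perm)) list() else perm
  permRec$q2Sequence <- q2s
  new("ValidationReport",
      r2y = numeric(0),
      q2ByScheme = if (!is.na(sel)) setNames(q2s[sel], as.character(nFolds))
                   else setNames(numeric(0), character(0)),
      selectedA = sel, status = status, permutation = permRec, seed = seed)
}

#' Fraction of response variance explained (R2Y)
#'
#' 1 - ||Yc - Yhat_c||^2_F / ||Yc||^2_F for the fitted model on its training
#' data.
#'
#' @param model a fitted discriminant model
#' @param X the (preprocessed) training matrix
#' @param Y the \linkS4class{ClassResponse} or label vector used in fitting
#' @return R2Y in (-Inf, 1]
#' @export
r2y <- function(model, X, Y) {
  if (!is(Y, "ClassResponse")) Y <- dummyCode(Y)
  Yc <- .centerCols(Y@Y)$centered
  tss <- sum(Yc^2)
  if (tss == 0) stop("Y has zero variance")
  Yhat <- predict(model, X)
  Yhatc <- sweep(Yhat, 2L, colMeans(Y@Y), "-")
  1 - sum((Yc - Yhatc)^2) / tss
}

#' Assemble a full validation report for one model
#'
#' Runs the fold schemes (default 6, 7, 8), the permutation test at the given
#' A, and the fitted R2Y, mirroring the reporting convention
#' "R2 = ..., Q2_6-fold, Q2_7-fold, Q2_8-fold".
#'
#' @inheritParams permutationTest
#' @param A the component count of the reported model
#' @param foldSchemes fold counts for the Q2 map
#' @return a \linkS4class{ValidationReport}
#' @export
validateModel <- function(recipe, X, labels, A, foldSchemes = c(6L, 7L, 8L),
                          nPerm = 400L, alpha = 0.05, seed = NULL) {
  if (is(X, "FeatureTable")) X <- intensities(X)
  q2s <- vapply(foldSchemes, function(nf)
    crossvalQ2(recipe, X, labels, A, nf, seed), numeric(1))
  names(q2s) <- as.character(foldSchemes)
  perm <- permutationTest(recipe, X, labels, A, nPerm,
                          nFolds = if (7L %in% foldSchemes) 7L
                                   else foldSchemes[1L],
                          alpha, seed)
  prep <- .estimatePreprocess(X, recipe)
  model <- .recipeFit(recipe, prep$X, dummyCode(labels), A,
                      seq_along(labels))
  new("ValidationReport",
      r2y = r2y(model, prep$X, labels),
      q2ByScheme = q2s, selectedA = as.integer(A),
      status = if (perm$passed) "accepted" else "rejected",
      permutation = perm, seed = seed)
}
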