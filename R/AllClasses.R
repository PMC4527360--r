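#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats predict cor median sd aov p.adjust runif rnorm setNames
#'   lm.fit aggregate ks.test
#' @importFrom utils read.csv write.csv modifyList
NULL

.FT_STATES <- c("raw", "normalized", "logged", "centered", "autoscaled")
.FT_STATE_RANK <- c(raw = 1L, normalized = 2L, logged = 3L,
                    centered = 4L, autoscaled = 4L)

.VINEYARD_MACROZONE <- c(
  BA = "LakeGarda", CS = "LakeGarda",
  BM = "Valpolicella", FA = "Valpolicella", MN = "Valpolicella",
  AM = "Soave", PM = "Soave")

#' FeatureTable: a sample x feature intensity matrix
#'
#' A \linkS4class{SummarizedExperiment} whose assay holds feature intensities
#' (features in rows, samples in columns, as usual for Bioconductor
#' containers), plus a \code{state} slot tracking the preprocessing stage.
#' Per-sample design factors live in \code{colData} and per-feature annotation
#' (chemical class, marker group, internal-standard key) in \code{rowData}.
#' User-facing accessors present the matrix in its sample x feature
#' orientation, the layout of the modelling functions.
#'
#' State moves only forward along
#' \code{raw -> normalized -> logged -> centered/autoscaled}; intensities must
#' be non-negative until the log transform.
#'
#' @slot state one of \code{"raw"}, \code{"normalized"}, \code{"logged"},
#'   \code{"centered"}, \code{"autoscaled"}
#' @aliases FeatureTable-class
#' @exportClass FeatureTable
setClass("FeatureTable",
  contains = "SummarizedExperiment",
  slots = c(state = "character"))

setValidity("FeatureTable", function(object) {
  msg <- character()
  if (length(object@state) != 1L || !object@state %in% .FT_STATES)
    msg <- c(msg, sprintf("state must be one of %s",
                          paste(.FT_STATES, collapse = ", ")))
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msg <- c(msg, "feature and sample identifiers are required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, sprintf("duplicate feature identifier: %s",
                          rownames(object)[duplicated(rownames(object))][1L]))
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, sprintf("duplicate sample identifier: %s",
                          colnames(object)[duplicated(colnames(object))][1L]))
  m <- SummarizedExperiment::assay(object)
  if (anyNA(m)) msg <- c(msg, "missing intensities are not allowed")
  if (length(object@state) == 1L && object@state %in% c("raw", "normalized") &&
      length(m) && min(m) < 0)
    msg <- c(msg, "negative intensities in a pre-log table")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureTable
#'
#' @param values numeric matrix, samples in rows and features in columns
#' @param state preprocessing state, default \code{"raw"}
#' @param design optional per-sample data.frame (see [studyDesign()])
#' @param annotation optional per-feature data.frame
#' @return a \linkS4class{FeatureTable}
#' @examples
#' x <- matrix(abs(rnorm(12)), 3, 4,
#'             dimnames = list(paste0("s", 1:3), paste0("f", 1:4)))
#' ft <- FeatureTable(x)
#' @export
FeatureTable <- function(values, state = "raw", design = NULL,
                         annotation = NULL) {
  values <- .checkMatrix(values, "values")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' needs sample rownames and feature colnames")
  args <- list(assays = list(intensity = t(values)))
  if (!is.null(design)) {
    design <- design[match(rownames(values), rownames(design)), , drop = FALSE]
    args$colData <- S4Vectors::DataFrame(design)
  }
  if (!is.null(annotation)) {
    annotation <- annotation[match(colnames(values), rownames(annotation)), ,
                             drop = FALSE]
    args$rowData <- S4Vectors::DataFrame(annotation)
  }
  se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
  new("FeatureTable", se, state = state)
}

#' Accessors for FeatureTable
#'
#' \code{intensities} returns the sample x feature matrix;
#' \code{tableState} the preprocessing state; \code{designTable} the
#' per-sample factors as a data.frame; \code{featureAnnotation} the
#' per-feature annotation.
#'
#' @param object a \linkS4class{FeatureTable}
#' @name featureTable-accessors
#' @aliases intensities tableState sampleIDs featureIDs designTable
#'   featureAnnotation
NULL

#' @rdname featureTable-accessors
#' @export
setMethod("intensities", "FeatureTable", function(object)
  t(SummarizedExperiment::assay(object)))

#' @rdname featureTable-accessors
#' @export
setMethod("tableState", "FeatureTable", function(object) object@state)

#' @rdname featureTable-accessors
#' @export
setMethod("sampleIDs", "FeatureTable", function(object) colnames(object))

#' @rdname featureTable-accessors
#' @export
setMethod("featureIDs", "FeatureTable", function(object) rownames(object))

#' @rdname featureTable-accessors
#' @export
setMethod("designTable", "FeatureTable", function(object)
  as.data.frame(SummarizedExperiment::colData(object)))

#' @rdname featureTable-accessors
#' @export
setMethod("featureAnnotation", "FeatureTable", function(object)
  as.data.frame(SummarizedExperiment::rowData(object)))

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d samples x %d features [state: %s]\n",
              ncol(object), nrow(object), object@state))
  callNextMethod()
})

# internal: replace the matrix, advancing the state
.updateTable <- function(object, values, state) {
  cur <- .FT_STATE_RANK[[object@state]]
  nxt <- .FT_STATE_RANK[[state]]
  if (nxt < cur)
    stop(sprintf("cannot move table state backwards (%s -> %s)",
                 object@state, state))
  SummarizedExperiment::assay(object) <- t(values)
  object@state <- state
  validObject(object)
  object
}

#' ClassResponse: dummy-coded class membership
#'
#' Holds the N-column 0/1 response matrix Y of a discriminant model, with the
#' class order fixed at first appearance so component signs are reproducible.
#'
#' @slot classes ordered class labels
#' @slot Y sample x N dummy matrix (one 1 per row)
#' @slot sourceFactor name of the design column the labels came from
#' @exportClass ClassResponse
setClass("ClassResponse",
  slots = c(classes = "character", Y = "matrix", sourceFactor = "character"))

setValidity("ClassResponse", function(object) {
  msg <- character()
  if (ncol(object@Y) != length(object@classes))
    msg <- c(msg, "Y must have one column per class")
  if (length(object@Y) && !all(rowSums(object@Y) == 1))
    msg <- c(msg, "each row of Y must contain exactly one 1")
  if (length(object@Y) && !all(object@Y %in% c(0, 1)))
    msg <- c(msg, "Y must be a 0/1 dummy matrix")
  if (length(msg)) msg else TRUE
})

#' ConstraintBlock: centered dummy codes of a nuisance factor
#'
#' The Z block against which oCPLS2-DA scores are constrained orthogonal.
#' All levels are kept (the block is rank-deficient); downstream projectors
#' use pseudo-inverses, so no reference level is dropped.
#'
#' @slot Z sample x c matrix of centered dummy codes (columns sum to zero)
#' @slot sourceFactor name of the design column
#' @exportClass ConstraintBlock
setClass("ConstraintBlock",
  slots = c(Z = "matrix", sourceFactor = "character"))

setValidity("ConstraintBlock", function(object) {
  if (length(object@Z) && max(abs(colSums(object@Z))) > 1e-10)
    "columns of Z must be centered" else TRUE
})

#' Latent-variable model classes
#'
#' \code{LatentModel} is the virtual parent of \code{PCAModel},
#' \code{PLSDAModel}, \code{OCPLSDAModel} (adds the constraint block) and
#' \code{OPLSDAModel} (adds the Y-orthogonal component triplet). Slots follow
#' the usual chemometric notation: scores T, X-loadings P, X-weights W,
#' Y-loadings C.
#'
#' @slot kind model kind string
#' @slot A number of components
#' @slot T sample x A score matrix
#' @slot P feature x A X-loading matrix
#' @slot W feature x A X-weight matrix (unit-norm columns)
#' @slot center,scale centering/scaling vectors applied to X before the fit
#'   (length 0 when the caller preprocessed externally)
#' @slot r2x fraction of X variance captured per component
#' @name LatentModel-classes
#' @aliases LatentModel-class PCAModel-class PLSDAModel-class
#'   OCPLSDAModel-class OPLSDAModel-class
#' @exportClass LatentModel
#' @exportClass PCAModel
#' @exportClass PLSDAModel
#' @exportClass OCPLSDAModel
#' @exportClass OPLSDAModel
setClass("LatentModel", representation("VIRTUAL",
  kind = "character", A = "integer",
  T = "matrix", P = "matrix", W = "matrix",
  center = "numeric", scale = "numeric",
  r2x = "numeric"))

#' @rdname LatentModel-classes
setClass("PCAModel", contains = "LatentModel")

#' @rdname LatentModel-classes
#' @slot C N x A Y-loading matrix
#' @slot classes class labels of the dummy response
#' @slot yMeans column means of the dummy Y removed before fitting
#' @slot r2yCum cumulative fraction of Y variance explained after each component
setClass("PLSDAModel", contains = "LatentModel",
  representation(C = "matrix", classes = "character",
                 yMeans = "numeric", r2yCum = "numeric"))

#' @rdname LatentModel-classes
#' @slot Z the constraint block the scores are orthogonal to
#' @slot constraintFactor name of the nuisance factor
setClass("OCPLSDAModel", contains = "PLSDAModel",
  representation(Z = "matrix", constraintFactor = "character"))

#' @rdname LatentModel-classes
#' @slot Wo,Po,To weight/loading/score matrices of the Y-orthogonal components
setClass("OPLSDAModel", contains = "PLSDAModel",
  representation(Wo = "matrix", Po = "matrix", To = "matrix"))

setValidity("LatentModel", function(object) {
  msg <- character()
  if (ncol(object@T) != object@A) msg <- c(msg, "T must have A columns")
  if (length(object@W)) {
    nrm <- sqrt(colSums(object@W^2))
    if (any(abs(nrm - 1) > 1e-6)) msg <- c(msg, "columns of W must be unit norm")
  }
  if (length(object@r2x) &&
      (any(object@r2x < -1e-10) || sum(object@r2x) > 1 + 1e-8))
    msg <- c(msg, "r2x must lie in [0,1] and sum to at most 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LatentModel", function(object) {
  cat(sprintf("%s model: %d component(s), %d samples x %d features\n",
              object@kind, object@A, nrow(object@T), nrow(object@P)))
  cat(sprintf("  R2X per component: %s\n",
              paste(sprintf("%.3f", object@r2x), collapse = " ")))
  if (is(object, "PLSDAModel"))
    cat(sprintf("  classes: %s; cumulative R2Y: %s\n",
                paste(object@classes, collapse = ", "),
                paste(sprintf("%.3f", object@r2yCum), collapse = " ")))
  if (is(object, "OPLSDAModel"))
    cat(sprintf("  orthogonal components: %d\n", ncol(object@To)))
  invisible(object)
})

#' @rdname model-generics
#' @export
setMethod("scores", "LatentModel", function(object, ...) object@T)
#' @rdname model-generics
#' @export
setMethod("xLoadings", "LatentModel", function(object, ...) object@P)
#' @rdname model-generics
#' @export
setMethod("xWeights", "LatentModel", function(object, ...) object@W)
#' @rdname model-generics
#' @export
setMethod("yLoadings", "PLSDAModel", function(object, ...) object@C)
#' @rdname model-generics
#' @export
setMethod("nComponents", "LatentModel", function(object) object@A)
#' @rdname model-generics
#' @export
setMethod("explainedVariance", "LatentModel", function(object) object@r2x)
#' @rdname model-generics
#' @export
setMethod("classLabels", "PLSDAModel", function(object) object@classes)
#' @rdname model-generics
#' @export
setMethod("orthScores", "OPLSDAModel", function(object) object@To)

#' PostTransformedModel: predictive / Y-orthogonal rotation of a PLS model
#'
#' The fitted weight matrix is rotated by an orthogonal G so that at most
#' N-1 components remain predictive for the N classes and the rest are
#' response-orthogonal; fitted responses are unchanged by the rotation.
#'
#' @slot base the fitted \linkS4class{PLSDAModel} (or subclass)
#' @slot G the A x A orthogonal rotation
#' @slot nPredictive number of predictive components (= rank of Yc'T)
#' @slot Tpred,Torth rotated score blocks
#' @slot Wpred,Worth rotated weight blocks
#' @slot Cpred rotated Y-loadings of the predictive block
#' @exportClass PostTransformedModel
setClass("PostTransformedModel",
  representation(base = "PLSDAModel", G = "matrix", nPredictive = "integer",
                 Tpred = "matrix", Torth = "matrix",
                 Wpred = "matrix", Worth = "matrix", Cpred = "matrix"))

setMethod("show", "PostTransformedModel", function(object) {
  cat(sprintf(
    "Post-transformed %s model: %d predictive + %d orthogonal component(s)\n",
    object@base@kind, object@nPredictive, ncol(object@Torth)))
  invisible(object)
})

#' @rdname model-generics
#' @export
setMethod("scores", "PostTransformedModel", function(object, ...) object@Tpred)
#' @rdname model-generics
#' @export
setMethod("orthScores", "PostTransformedModel", function(object) object@Torth)
#' @rdname model-generics
#' @export
setMethod("nComponents", "PostTransformedModel", function(object)
  object@nPredictive)

#' ValidationReport: cross-validation and permutation summary of one model
#'
#' @slot r2y fitted R2Y
#' @slot q2ByScheme named Q2 values, one per fold count (e.g. "6","7","8")
#' @slot selectedA selected number of components (NA when rejected)
#' @slot status "accepted", "rejected" or "not-estimable"
#' @slot permutation list with observedQ2, nullQ2, pValue, passed, nPerm
#' @slot seed the seed used for fold shuffling / permutations
#' @exportClass ValidationReport
setClass("ValidationReport",
  representation(r2y = "numeric", q2ByScheme = "numeric",
                 selectedA = "integer", status = "character",
                 permutation = "list", seed = "ANY"))

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport [%s]: A = %s, R2Y = %.3f\n", object@status,
              ifelse(is.na(object@selectedA), "-", object@selectedA),
              if (length(object@r2y)) object@r2y else NA_real_))
  if (length(object@q2ByScheme))
    cat("  Q2:", paste(sprintf("%s-fold %.3f", names(object@q2ByScheme),
                               object@q2ByScheme), collapse = ", "), "\n")
  if (length(object@permutation))
    cat(sprintf("  permutation: p = %.4g (%d permutations), %s\n",
                object@permutation$pValue, object@permutation$nPerm,
                if (isTRUE(object@permutation$passed)) "passed" else "failed"))
  invisible(object)
})
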