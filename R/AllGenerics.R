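#' @title Generics for latent-variable models
#' @description Accessor generics shared by the PCA / PLS-DA / oCPLS2-DA /
#'   OPLS-DA model classes. All models expose scores, X-loadings and X-weights;
#'   discriminant models additionally expose Y-loadings and class labels.
#' @param object a fitted model object
#' @param ... further arguments for methods
#' @name model-generics
NULL

#' @rdname model-generics
#' @export
setGeneric("scores", function(object, ...) standardGeneric("scores"))

#' @rdname model-generics
#' @export
setGeneric("xLoadings", function(object, ...) standardGeneric("xLoadings"))

#' @rdname model-generics
#' @export
setGeneric("xWeights", function(object, ...) standardGeneric("xWeights"))

#' @rdname model-generics
#' @export
setGeneric("yLoadings", function(object, ...) standardGeneric("yLoadings"))

#' @rdname model-generics
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))

#' @rdname model-generics
#' @export
setGeneric("explainedVariance", function(object) standardGeneric("explainedVariance"))

#' @rdname model-generics
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))

#' @rdname model-generics
#' @export
setGeneric("orthScores", function(object) standardGeneric("orthScores"))

#' Classify new samples with a fitted discriminant model
#'
#' @param object a fitted discriminant model
#' @param newdata matrix of new observations, preprocessed like the training
#'   data
#' @param ... further arguments for methods
#' @return character vector of predicted class labels
#' @export
setGeneric("classify", function(object, newdata, ...) standardGeneric("classify"))

#' @rdname featureTable-accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname featureTable-accessors
#' @export
setGeneric("tableState", function(object) standardGeneric("tableState"))

#' @rdname featureTable-accessors
#' @export
setGeneric("sampleIDs", function(object) standardGeneric("sampleIDs"))

#' @rdname featureTable-accessors
#' @export
setGeneric("featureIDs", function(object) standardGeneric("featureIDs"))

#' @rdname featureTable-accessors
#' @export
setGeneric("designTable", function(object) standardGeneric("designTable"))

#' @rdname featureTable-accessors
#' @export
setGeneric("featureAnnotation", function(object) standardGeneric("featureAnnotation"))

#' Write the score/loading/weight tables of a fitted model
#'
#' @param model a fitted model (or post-transformed model)
#' @param outDir directory to write into (created if absent)
#' @param prefix file-name prefix
#' @return invisibly, the paths written
#' @export
setGeneric("writeModelTables", function(model, outDir, prefix = "model")
  standardGeneric("writeModelTables"))
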