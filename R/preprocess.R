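#' Internal-standard normalization
#'
#' Divides each feature intensity by the peak area of the internal standard
#' assigned to its compound class in that sample: monoterpenes and
#' sesquiterpenes to alpha-copaene, norisoprenoids to d3-beta-ionone, all
#' remaining compounds to d13-hexanol. The mapping is carried per feature in
#' the annotation's \code{internal_standard_key} column.
#'
#' @param table a \linkS4class{FeatureTable} in state raw
#' @param annotation data.frame with an \code{internal_standard_key} column,
#'   rownames = feature ids (defaults to the table's own annotation)
#' @param isAreas sample x internal-standard matrix of peak areas, columns
#'   named by standard; all areas strictly positive
#' @return the normalized \linkS4class{FeatureTable} (state
#'   \code{normalized})
#' @export
internalStandardNormalize <- function(table, annotation = NULL, isAreas) {
  if (is.null(annotation)) annotation <- featureAnnotation(table)
  if (!"internal_standard_key" %in% colnames(annotation))
    stop("annotation lacks an 'internal_standard_key' column")
  keys <- annotation[featureIDs(table), "internal_standard_key"]
  if (anyNA(keys))
    stop("every feature needs an internal_standard_key before IS normalization")
  isAreas <- as.matrix(isAreas)
  missingIS <- setdiff(unique(keys), c(colnames(isAreas), "none"))
  if (length(missingIS))
    stop("no areas provided for internal standard(s): ",
         paste(missingIS, collapse = ", "))
  bad <- which(isAreas <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-positive area for internal standard '%s' in sample '%s'",
                 colnames(isAreas)[bad[1L, 2L]],
                 rownames(isAreas)[bad[1L, 1L]] %||% bad[1L, 1L]))
  m <- intensities(table)
  div <- matrix(1, nrow(m), ncol(m))
  use <- keys != "none"
  div[, use] <- isAreas[, keys[use], drop = FALSE]
  .updateTable(table, m / div, "normalized")
}

#' Median fold change normalization
#'
#' Removes per-sample dilution: the reference profile is the per-feature
#' median across all samples; each sample's dilution factor is the median,
#' over features positive in both the sample and the reference, of
#' intensity/reference; the sample is divided by its factor.
#'
#' The estimated reference profile is returned so held-out samples (or an
#' already-normalized table) can be normalized against the same reference:
#' renormalizing a normalized table against its own stored reference yields
#' factors of exactly 1.
#'
#' @param table a \linkS4class{FeatureTable} (state raw or normalized),
#'   intensities >= 0
#' @param reference optional per-feature reference profile; defaults to the
#'   per-feature median of \code{table}
#' @return list with \code{table} (normalized \linkS4class{FeatureTable}),
#'   \code{factors} (named per-sample dilution factors) and
#'   \code{reference}
#' @export
medianFoldChangeNormalize <- function(table, reference = NULL) {
  m <- intensities(table)
  if (min(m) < 0) stop("median fold change normalization needs intensities >= 0")
  ref <- if (is.null(reference)) apply(m, 2L, median) else reference
  factors <- vapply(seq_len(nrow(m)), function(i) {
    ok <- ref > 0 & m[i, ] > 0
    if (!any(ok))
      stop("sample '", rownames(m)[i],
           "' shares no positive feature with the reference profile")
    median(m[i, ok] / ref[ok])
  }, numeric(1))
  names(factors) <- rownames(m)
  list(table = .updateTable(table, m / factors, "normalized"),
       factors = factors, reference = ref)
}

#' Log transformation
#'
#' Natural log with a small positive offset for zero intensities:
#' x -> ln(x + epsilon). The base is immaterial once the data are centered or
#' autoscaled; epsilon defaults to one raw-intensity unit.
#'
#' @param table a \linkS4class{FeatureTable} with intensities >= 0
#' @param epsilon positive offset added before the log
#' @return the transformed table (state \code{logged})
#' @export
logTransform <- function(table, epsilon = 1) {
  m <- intensities(table)
  if (min(m) < 0) stop("negative intensity: log transform needs x >= 0")
  if (epsilon <= 0) stop("'epsilon' must be positive")
  .updateTable(table, log(m + epsilon), "logged")
}

#' Mean centering and autoscaling
#'
#' \code{meanCenter} removes the per-feature mean; \code{autoscale}
#' additionally divides by the per-feature sample standard deviation
#' (n - 1 denominator). The fitted means/sds are returned so held-out data
#' can be transformed with training-set parameters during cross-validation
#' (see [applyScaling()]).
#'
#' @param table a \linkS4class{FeatureTable}
#' @return list with \code{table} and the fitted \code{means} (and \code{sds}
#'   for autoscale)
#' @export
meanCenter <- function(table) {
  m <- intensities(table)
  if (nrow(m) < 2L) stop("centering needs at least 2 samples")
  mu <- colMeans(m)
  list(table = .updateTable(table, sweep(m, 2L, mu, "-"), "centered"),
       means = mu)
}

#' @rdname meanCenter
#' @export
autoscale <- function(table) {
  m <- intensities(table)
  if (nrow(m) < 2L) stop("autoscaling needs at least 2 samples")
  mu <- colMeans(m)
  sds <- apply(m, 2L, sd)
  zero <- sds < .Machine$double.eps^0.5
  if (any(zero))
    stop("zero-variance feature(s) cannot be autoscaled: ",
         paste(colnames(m)[zero], collapse = ", "))
  out <- sweep(sweep(m, 2L, mu, "-"), 2L, sds, "/")
  list(table = .updateTable(table, out, "autoscaled"), means = mu, sds = sds)
}

#' Apply stored centering/scaling parameters to new data
#'
#' @param values sample x feature matrix (or \linkS4class{FeatureTable})
#' @param means per-feature means from the training set
#' @param sds optional per-feature standard deviations (autoscaling)
#' @return the transformed matrix
#' @export
applyScaling <- function(values, means, sds = NULL) {
  m <- if (is(values, "FeatureTable")) intensities(values) else values
  m <- sweep(m, 2L, means, "-")
  if (!is.null(sds)) m <- sweep(m, 2L, sds, "/")
  m
}

# --- recipe-driven preprocessing used inside cross-validation ---------------

# estimate preprocessing parameters on a training matrix (raw scale)
.estimatePreprocess <- function(X, recipe) {
  params <- list()
  if (recipe@mfc) {
    params$mfcRef <- apply(X, 2L, median)
    X <- X / .mfcFactors(X, params$mfcRef)
  }
  if (recipe@log) X <- log(X + recipe@epsilon)
  if (recipe@scaling == "autoscale") {
    params$means <- colMeans(X)
    params$sds <- apply(X, 2L, sd)
    if (any(params$sds < .Machine$double.eps^0.5))
      stop("zero-variance feature in training fold under autoscaling")
    X <- sweep(sweep(X, 2L, params$means, "-"), 2L, params$sds, "/")
  } else if (recipe@scaling == "center") {
    params$means <- colMeans(X)
    X <- sweep(X, 2L, params$means, "-")
  }
  list(X = X, params = params)
}

.mfcFactors <- function(X, ref) {
  vapply(seq_len(nrow(X)), function(i) {
    ok <- ref > 0 & X[i, ] > 0
    if (!any(ok)) stop("sample shares no positive feature with the reference")
    median(X[i, ok] / ref[ok])
  }, numeric(1))
}

# apply training-fold parameters to held-out rows
.applyPreprocess <- function(X, recipe, params) {
  if (recipe@mfc) X <- X / .mfcFactors(X, params$mfcRef)
  if (recipe@log) X <- log(X + recipe@epsilon)
  if (!is.null(params$means)) X <- sweep(X, 2L, params$means, "-")
  if (!is.null(params$sds)) X <- sweep(X, 2L, params$sds, "/")
  X
}
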