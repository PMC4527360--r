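#' Correlation loadings (pq(corr)) of a post-transformed model
#'
#' For every feature j and predictive component a, p(corr) is the Pearson
#' correlation of the feature column with the predictive score t_a; for
#' every class k, q(corr) is the correlation of the centered dummy response
#' column with t_a. Stacked, the two make the plot-ready "pq(corr)" structure
#' of a correlation loading plot.
#'
#' @param model a \linkS4class{PostTransformedModel} (or any fitted model,
#'   whose plain scores are then used)
#' @param X the preprocessed training matrix (or
#'   \linkS4class{FeatureTable})
#' @param Y the \linkS4class{ClassResponse} or label vector used in fitting
#' @return list with \code{pCorr} (feature x component), \code{qCorr}
#'   (class x component); zero-variance features get NA and are listed in
#'   attribute \code{flagged}
#' @export
correlationLoadings <- function(model, X, Y) {
  if (is(X, "FeatureTable")) X <- intensities(X)
  if (!is(Y, "ClassResponse")) Y <- dummyCode(Y)
  Tm <- scores(model)
  if (!ncol(Tm)) stop("model has no predictive components")
  sdX <- apply(X, 2L, sd)
  flagged <- colnames(X)[sdX == 0] %||% character(0)
  pCorr <- suppressWarnings(cor(X, Tm))
  pCorr[sdX == 0, ] <- NA_real_
  qCorr <- cor(.centerCols(Y@Y)$centered, Tm)
  colnames(pCorr) <- colnames(qCorr) <- paste0("t", seq_len(ncol(Tm)))
  rownames(qCorr) <- Y@classes
  structure(list(pCorr = pCorr, qCorr = qCorr), flagged = flagged)
}

#' Extract class markers from correlation loadings
#'
#' A feature is a marker when |p(corr)| exceeds the threshold on at least one
#' predictive component. On the component where it correlates most strongly,
#' the feature is assigned to the class whose q(corr) is best aligned with
#' its direction; when the best alignment is opposite in sign the feature is
#' a negative marker of that class (low levels characterise the class).
#'
#' @param pq output of [correlationLoadings()]
#' @param annotation optional per-feature data.frame with
#'   \code{chemical_class} and/or \code{marker_group} columns
#' @param threshold |p(corr)| cutoff in (0, 1]; 0.75 is the usual "strong"
#'   cutoff for single-feature association models, 0.5 a common screening
#'   default
#' @return data.frame (one row per marker feature): feature, component,
#'   pq_corr, class, sign, plus annotation columns when given
#' @export
extractMarkers <- function(pq, annotation = NULL, threshold = 0.5) {
  if (threshold <= 0 || threshold > 1)
    stop("'threshold' must be in (0, 1]")
  pC <- pq$pCorr; qC <- pq$qCorr
  hit <- which(apply(abs(pC) > threshold, 1L, any, na.rm = TRUE))
  rows <- lapply(hit, function(j) {
    a <- which.max(abs(pC[j, ]))
    align <- pC[j, a] * qC[, a]
    k <- which.max(abs(align))
    data.frame(feature = rownames(pC)[j] %||% as.character(j),
               component = a,
               pq_corr = unname(pC[j, a]),
               class = rownames(qC)[k],
               sign = ifelse(align[k] >= 0, "positive", "negative"))
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(feature = character(0), component = integer(0),
                         pq_corr = numeric(0), class = character(0),
                         sign = character(0))
  rownames(out) <- NULL
  if (!is.null(annotation) && nrow(out)) {
    keep <- intersect(c("chemical_class", "marker_group"),
                      colnames(annotation))
    out <- cbind(out, annotation[out$feature, keep, drop = FALSE])
    rownames(out) <- NULL
  }
  out
}

#' Aggregate marker groups by vineyard and vintage
#'
#' For each marker group (e.g. an anthocyanin or flavonoid cluster), the mean
#' normalized intensity (arbitrary units) of the member features over the
#' replicate samples of every vineyard x vintage combination — the data
#' behind per-vineyard marker bar charts. The mean (not the sum) is used so
#' the value does not scale with group size.
#'
#' @param table a normalized \linkS4class{FeatureTable} (or sample x feature
#'   matrix)
#' @param markers data.frame from [extractMarkers()] with a
#'   \code{marker_group} column (or a feature->group map supplied via
#'   \code{groups})
#' @param design a [studyDesign()] data.frame aligned with the samples
#' @param groups optional named character vector mapping features to groups,
#'   overriding the markers' \code{marker_group}
#' @return long-format data.frame: group, vineyard, vintage, value
#' @export
aggregateMarkerGroups <- function(table, markers, design, groups = NULL) {
  m <- if (is(table, "FeatureTable")) intensities(table) else table
  if (is.null(groups)) {
    if (!"marker_group" %in% colnames(markers))
      stop("markers lack a 'marker_group' column; supply 'groups'")
    groups <- setNames(as.character(markers$marker_group), markers$feature)
  }
  groups <- groups[!is.na(groups) & groups != ""]
  out <- list()
  for (g in unique(groups)) {
    members <- intersect(names(groups)[groups == g], colnames(m))
    if (!length(members)) {
      warning("marker group '", g, "' has no member features; omitted")
      next
    }
    sub <- rowMeans(m[, members, drop = FALSE])
    agg <- aggregate(sub,
                     by = list(vineyard = design$vineyard,
                               vintage = design$vintage),
                     FUN = mean)
    out[[g]] <- data.frame(group = g, vineyard = agg$vineyard,
                           vintage = agg$vintage, value = agg$x)
  }
  if (!length(out))
    return(data.frame(group = character(0), vineyard = character(0),
                      vintage = character(0), value = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
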