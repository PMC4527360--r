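#' Read a delimited feature table
#'
#' Reads a comma-separated intensity table (UTF-8, one header row, one leading
#' identifier column) into a \linkS4class{FeatureTable} in state \code{raw}.
#' The default layout is samples in rows and features in columns, the common
#' peak-table export; \code{orientation = "features_in_rows"} accepts the
#' transposed layout.
#'
#' @param path path to a CSV file
#' @param orientation \code{"samples_in_rows"} (default) or
#'   \code{"features_in_rows"}
#' @return a \linkS4class{FeatureTable} in state \code{raw}
#' @export
readFeatureTable <- function(path,
                             orientation = c("samples_in_rows",
                                             "features_in_rows")) {
  orientation <- match.arg(orientation)
  raw <- read.csv(path, header = TRUE, check.names = FALSE,
                  stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("empty feature table: ", path)
  rowIDs <- raw[[1L]]
  colIDs <- colnames(raw)[-1L]
  if (anyDuplicated(rowIDs))
    stop("duplicate identifier in first column: ",
         rowIDs[duplicated(rowIDs)][1L])
  if (anyDuplicated(colIDs))
    stop("duplicate identifier in header: ",
         colIDs[duplicated(colIDs)][1L])
  vals <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(rowIDs, colIDs))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric or missing cell at row '%s', column '%s'",
                 rowIDs[bad[1L]], colIDs[bad[2L]]))
  }
  if (orientation == "features_in_rows") vals <- t(vals)
  FeatureTable(vals, state = "raw")
}

#' Write a FeatureTable to CSV
#'
#' Samples in rows, features in columns; values round-trip losslessly through
#' [readFeatureTable()] (better than 1e-10 relative).
#'
#' @param table a \linkS4class{FeatureTable}
#' @param path output path
#' @return invisibly, \code{path}
#' @export
writeFeatureTable <- function(table, path) {
  m <- intensities(table)
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a validated study design table
#'
#' Validates the per-sample factor table of the vineyard study layout:
#' vineyard, vintage, developmental stage and replicate pool, with the
#' macrozone derived from the fixed vineyard-to-macrozone map (BA, CS in Lake
#' Garda; BM, FA, MN in Valpolicella; AM, PM in Soave) when absent.
#'
#' @param df data.frame with columns \code{vineyard}, \code{vintage},
#'   \code{stage}, \code{replicate} and optionally \code{macrozone}; rownames
#'   are sample identifiers
#' @return a data.frame with all five factors, rownames = sample ids
#' @export
studyDesign <- function(df) {
  need <- c("vineyard", "vintage", "stage", "replicate")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("design is missing column(s): ", paste(miss, collapse = ", "))
  df$vineyard <- as.character(df$vineyard)
  if (!"macrozone" %in% colnames(df)) {
    unknown <- setdiff(unique(df$vineyard), names(.VINEYARD_MACROZONE))
    if (length(unknown))
      stop("unknown vineyard code(s) with no macrozone given: ",
           paste(unknown, collapse = ", "))
    df$macrozone <- unname(.VINEYARD_MACROZONE[df$vineyard])
  }
  df[, c("vineyard", "macrozone", "vintage", "stage", "replicate")]
}

#' Read a sample design table
#'
#' @param path CSV with a leading sample-id column and the design factors
#' @param samples sample identifiers the design must cover (usually
#'   \code{sampleIDs(table)})
#' @return a validated design data.frame, rows ordered as \code{samples}
#' @export
readDesign <- function(path, samples) {
  df <- read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  rownames(df) <- df[[1L]]
  df <- df[-1L]
  missing <- setdiff(samples, rownames(df))
  if (length(missing))
    stop("samples absent from design: ", paste(missing, collapse = ", "))
  studyDesign(df[samples, , drop = FALSE])
}

#' Read a feature annotation table
#'
#' @param path CSV with a leading feature-id column and columns such as
#'   \code{chemical_class}, \code{marker_group}, \code{internal_standard_key}
#' @param features feature identifiers the annotation must cover
#' @return data.frame ordered as \code{features}
#' @export
readAnnotation <- function(path, features) {
  df <- read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  rownames(df) <- df[[1L]]
  df <- df[-1L]
  missing <- setdiff(features, rownames(df))
  if (length(missing))
    stop("features absent from annotation: ", paste(missing, collapse = ", "))
  df[features, , drop = FALSE]
}

#' Dummy-code class labels
#'
#' Builds the 0/1 response matrix of a discriminant model. Class order is
#' first-appearance order and is stored so component signs are reproducible.
#'
#' @param labels per-sample class labels (character or factor)
#' @param sourceFactor name of the design column the labels came from
#' @return a \linkS4class{ClassResponse}
#' @examples
#' dummyCode(c("a", "b", "a"))
#' @export
dummyCode <- function(labels, sourceFactor = NA_character_) {
  classes <- if (is.factor(labels)) levels(labels)
             else unique(as.character(labels))
  labels <- as.character(labels)
  if (length(classes) < 2L)
    stop("discrimination needs >=2 classes")
  Y <- vapply(classes, function(k) as.numeric(labels == k),
              numeric(length(labels)))
  Y <- matrix(Y, nrow = length(labels), dimnames = list(NULL, classes))
  new("ClassResponse", classes = classes, Y = Y,
      sourceFactor = as.character(sourceFactor))
}

#' Build the nuisance constraint block
#'
#' Dummy-codes the nuisance labels and centers every column. All levels are
#' kept, so the block has rank (levels - 1); downstream projectors use
#' pseudo-inverses and are unaffected by the rank deficiency.
#'
#' @param labels per-sample nuisance-factor labels (e.g. vintages)
#' @param sourceFactor name of the design column
#' @return a \linkS4class{ConstraintBlock}
#' @export
buildConstraintBlock <- function(labels, sourceFactor = NA_character_) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("constraint factor has a single level; pass no constraint instead")
  Y <- dummyCode(labels)@Y
  new("ConstraintBlock", Z = .centerCols(Y)$centered,
      sourceFactor = as.character(sourceFactor))
}

# write one numeric matrix as CSV with an id column; full double precision
.writeMatrixCSV <- function(m, path, idName = "id") {
  df <- data.frame(rownames(m) %||% as.character(seq_len(nrow(m))), m,
                   check.names = FALSE)
  colnames(df)[1L] <- idName
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a matrix written by [writeModelTables()]
#'
#' @param path CSV path with a leading id column
#' @return numeric matrix with rownames from the id column
#' @export
readModelTable <- function(path) {
  df <- read.csv(path, header = TRUE, check.names = FALSE,
                 stringsAsFactors = FALSE)
  m <- as.matrix(df[-1L])
  rownames(m) <- df[[1L]]
  m
}

.namedScores <- function(T, prefix = "t") {
  colnames(T) <- paste0(prefix, seq_len(ncol(T)))
  T
}

#' @describeIn writeModelTables scores (t1, t2, ...), X-loadings, X-weights
#'   and, for discriminant models, Y-loadings, each as one CSV
#' @export
setMethod("writeModelTables", "LatentModel", function(model, outDir,
                                                      prefix = "model") {
  if (model@A < 1L || !length(model@T)) stop("model is not fitted")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  f <- function(name) file.path(outDir, paste0(prefix, "_", name, ".csv"))
  paths <- c(
    .writeMatrixCSV(.namedScores(model@T), f("scores"), "sample"),
    .writeMatrixCSV(.namedScores(model@P, "p"), f("loadings"), "feature"),
    .writeMatrixCSV(.namedScores(model@W, "w"), f("weights"), "feature"))
  if (is(model, "PLSDAModel")) {
    C <- model@C
    rownames(C) <- model@classes
    paths <- c(paths, .writeMatrixCSV(.namedScores(C, "c"), f("yloadings"),
                                      "class"))
  }
  invisible(paths)
})

#' @describeIn writeModelTables predictive and orthogonal scores/weights of a
#'   post-transformed model; the (tp1, tp2) scores are the plot-ready pair of
#'   a 2-D score scatter
#' @export
setMethod("writeModelTables", "PostTransformedModel",
          function(model, outDir, prefix = "model") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  f <- function(name) file.path(outDir, paste0(prefix, "_", name, ".csv"))
  paths <- c(
    .writeMatrixCSV(.namedScores(model@Tpred, "tp"), f("scores_pred"), "sample"),
    .writeMatrixCSV(.namedScores(model@Wpred, "wp"), f("weights_pred"),
                    "feature"))
  if (ncol(model@Torth))
    paths <- c(paths,
      .writeMatrixCSV(.namedScores(model@Torth, "to"), f("scores_orth"),
                      "sample"))
  invisible(paths)
})
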