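#' Split-plot ANOVA for one feature
#'
#' Univariate screen for a design with restricted randomization: sampling is
#' nested in year, so year and replicate are whole-plot factors (tested
#' against the year x replicate whole-plot error stratum) while the producer
#' (vineyard) is the subplot factor (tested against the residual). The
#' additive model is
#' \code{y = mu + year + replicate + wholeplot_error + producer + residual};
#' an optional year:producer interaction can be added against the residual.
#'
#' The strata are fitted with \code{stats::aov} and an \code{Error()} term;
#' sums of squares are sequential, which on the balanced design equals the
#' cell-means decomposition.
#'
#' @param values per-sample numeric response (one feature)
#' @param design a [studyDesign()] data.frame aligned with \code{values};
#'   needs columns \code{vintage}, \code{replicate}, \code{vineyard}
#' @param interaction add a year:producer term tested against the residual
#' @return data.frame with rows year, replicate, wholeplot_error, producer,
#'   (interaction,) residual and columns factor, df, SS, MS, F, p; attribute
#'   \code{degenerate} is TRUE for a constant response
#' @export
splitPlotAnova <- function(values, design, interaction = FALSE) {
  if (length(values) != nrow(design))
    stop("'values' and 'design' differ in length")
  year <- factor(design$vintage)
  rep_ <- factor(design$replicate)
  prod_ <- factor(design$vineyard)
  if (nlevels(rep_) < 2L)
    stop("the whole-plot error stratum needs >= 2 replicate levels")
  if (nlevels(year) < 2L) stop("need >= 2 year levels")
  cells <- table(year, rep_)
  if (any(cells == 0L))
    stop("empty year x replicate cell(s); the whole-plot layout is incomplete")
  wholePlot <- interaction(year, rep_, drop = TRUE)
  d <- data.frame(y = values, year = year, replicate = rep_,
                  producer = prod_, wholePlot = wholePlot)
  form <- if (interaction)
    y ~ year + replicate + producer + year:producer + Error(wholePlot)
  else
    y ~ year + replicate + producer + Error(wholePlot)
  fit <- aov(form, data = d)
  s <- summary(fit)
  wp <- as.data.frame(s[["Error: wholePlot"]][[1L]])
  wi <- as.data.frame(s[["Error: Within"]][[1L]])
  rn <- function(tab) trimws(rownames(tab))
  pick <- function(tab, term) {
    i <- match(term, rn(tab))
    if (is.na(i)) stop("ANOVA stratum lacks term '", term, "'")
    unlist(tab[i, c("Df", "Sum Sq", "Mean Sq", "F value", "Pr(>F)")],
           use.names = FALSE)
  }
  rows <- list(
    year = pick(wp, "year"),
    replicate = pick(wp, "replicate"),
    wholeplot_error = pick(wp, "Residuals"),
    producer = pick(wi, "producer"))
  if (interaction) rows$interaction <- pick(wi, "year:producer")
  rows$residual <- pick(wi, "Residuals")
  out <- data.frame(factor = names(rows),
                    do.call(rbind, rows), row.names = NULL)
  colnames(out) <- c("factor", "df", "SS", "MS", "F", "p")
  # error strata carry no F/p of their own
  out[out$factor %in% c("wholeplot_error", "residual"), c("F", "p")] <- NA
  totSS <- sum((values - mean(values))^2)
  degenerate <- totSS < .Machine$double.eps * length(values)
  if (degenerate) out[, c("F", "p")] <- NA
  if (out$df[out$factor == "residual"] == 0L)
    out[out$factor == "producer", c("F", "p")] <- NA
  attr(out, "degenerate") <- degenerate
  out
}

#' Per-feature split-plot ANOVA screen
#'
#' Runs [splitPlotAnova()] on every feature of a (preprocessed) table and
#' tabulates the year and producer p-values, mirroring the univariate
#' pre-analysis that counts how many metabolites vary with vintage and with
#' producer. No multiple-testing correction is applied by default (the
#' screen reports raw significance fractions); Benjamini-Hochberg adjustment
#' is available behind a flag.
#'
#' @param table a \linkS4class{FeatureTable} (or sample x feature matrix)
#' @param design a [studyDesign()] data.frame aligned with the samples
#' @param alpha significance level for the reported fractions
#' @param adjust apply Benjamini-Hochberg adjustment to each p-value column
#'   before thresholding
#' @return list with \code{perFeature} (feature, p_year, p_producer,
#'   sig_year, sig_producer, failed) and the fractions \code{fracYear},
#'   \code{fracProducer} among non-failed features
#' @export
anovaScreen <- function(table, design, alpha = 0.05, adjust = FALSE) {
  m <- if (is(table, "FeatureTable")) intensities(table) else table
  if (ncol(m) == 0L)
    return(list(perFeature = data.frame(feature = character(0),
                                        p_year = numeric(0),
                                        p_producer = numeric(0),
                                        sig_year = logical(0),
                                        sig_producer = logical(0),
                                        failed = logical(0)),
                fracYear = NA_real_, fracProducer = NA_real_))
  res <- lapply(seq_len(ncol(m)), function(j) {
    tryCatch({
      tab <- splitPlotAnova(m[, j], design)
      c(p_year = tab$p[tab$factor == "year"],
        p_producer = tab$p[tab$factor == "producer"])
    }, error = function(e) c(p_year = NA_real_, p_producer = NA_real_))
  })
  res <- do.call(rbind, res)
  pYear <- res[, "p_year"]; pProd <- res[, "p_producer"]
  if (adjust) {
    pYear <- p.adjust(pYear, "BH")
    pProd <- p.adjust(pProd, "BH")
  }
  failed <- is.na(pYear) & is.na(pProd)
  perFeature <- data.frame(
    feature = colnames(m) %||% as.character(seq_len(ncol(m))),
    p_year = pYear, p_producer = pProd,
    sig_year = !is.na(pYear) & pYear < alpha,
    sig_producer = !is.na(pProd) & pProd < alpha,
    failed = failed)
  list(perFeature = perFeature,
       fracYear = mean(perFeature$sig_year[!failed]),
       fracProducer = mean(perFeature$sig_producer[!failed]))
}
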