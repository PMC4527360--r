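#' Specification for the synthetic study generator
#'
#' Describes a multi-vineyard, multi-vintage factorial berry study: 7
#' vineyards nested in 3 macrozones, 3 vintages, 3 developmental stages and
#' 3 replicate pools (189 samples), with feature intensities drawn from a
#' log-normal model — additive factor effects on the log scale, then
#' exponentiation and a per-sample dilution factor so that median fold
#' change normalization has something to remove.
#'
#' The default effect sizes put the study in the confounded regime: the
#' vintage effect standard deviation is three times the macrozone effect
#' standard deviation, so unconstrained models latch onto vintage. Effects
#' are drawn once per (feature, level); each feature carries each effect
#' with the stated fraction. The stage effect is monotone per feature with
#' random sign.
#'
#' @param nFeatures number of features (551 emulates an LC-MS peak table,
#'   48 a GC-MS table)
#' @param vineyards vineyard codes (must be in the fixed macrozone map)
#' @param vintages,stages,replicates design levels
#' @param baselineMean,baselineSd log-scale baseline abundance per feature
#' @param nGroups number of chemical-class-like feature groups; climate and
#'   the shared part of the site effect act coherently on group-level
#'   activities, reproducing the correlated covariance structure of real
#'   metabolomes
#' @param loadingSd spread of the per-feature loadings on their group
#'   activity (loadings are centred at 1)
#' @param stageSd per-feature monotone stage-trend standard deviation
#' @param vintageSd group-activity standard deviation of the vintage
#'   (climate) effect
#' @param macrozoneSd group-activity standard deviation of the shared site
#'   effect (defaults keep vintageSd = 3 x macrozoneSd, the confounded
#'   regime)
#' @param macrozoneFeatureSd,vineyardSd per-feature (site-specific)
#'   macrozone and vineyard-within-macrozone effect standard deviations
#' @param noiseSd replicate-level noise standard deviation
#' @param stageFrac,vintageFrac,macrozoneFrac,vineyardFrac fraction of
#'   features carrying each effect
#' @param dilution draw per-sample dilution factors (log-uniform in
#'   \code{dilutionRange})
#' @param dilutionRange range of the dilution factors
#' @param markerGroups optional named list; each element
#'   \code{list(nFeatures =, macrozone =, logFC =)} plants a feature group
#'   elevated by \code{logFC} in one macrozone
#' @param seed generator seed (same seed, same output, bitwise)
#' @return a list of class \code{SyntheticSpec}
#' @export
syntheticSpec <- function(nFeatures = 551L,
                          vineyards = c("AM", "BA", "BM", "CS", "FA", "MN",
                                        "PM"),
                          vintages = c(2006L, 2007L, 2008L),
                          stages = 1:3, replicates = 1:3,
                          baselineMean = 8, baselineSd = 1,
                          nGroups = 8L, loadingSd = 0.3,
                          stageSd = 0.6, vintageSd = 1,
                          macrozoneSd = 1 / 3,
                          macrozoneFeatureSd = 0.1, vineyardSd = 0.1,
                          noiseSd = 0.4,
                          stageFrac = 0.6, vintageFrac = 0.67,
                          macrozoneFrac = 0.7, vineyardFrac = 0.7,
                          dilution = TRUE, dilutionRange = c(0.5, 2),
                          markerGroups = NULL, seed = NULL) {
  spec <- structure(as.list(environment()), class = "SyntheticSpec")
  sds <- c(stageSd, vintageSd, macrozoneSd, macrozoneFeatureSd, vineyardSd,
           noiseSd, baselineSd)
  if (any(sds < 0)) stop("effect standard deviations must be >= 0")
  fr <- c(stageFrac, vintageFrac, macrozoneFrac, vineyardFrac)
  if (any(fr < 0 | fr > 1)) stop("effect fractions must lie in [0, 1]")
  unknown <- setdiff(vineyards, names(.VINEYARD_MACROZONE))
  if (length(unknown))
    stop("unknown vineyard code(s): ", paste(unknown, collapse = ", "))
  spec
}

#' Generate the full factorial study design
#'
#' @param spec a [syntheticSpec()]
#' @return a [studyDesign()] data.frame, one row per
#'   vineyard x vintage x stage x replicate combination (189 rows with the
#'   defaults), rownames = sample ids
#' @export
generateDesign <- function(spec = syntheticSpec()) {
  g <- expand.grid(replicate = spec$replicates, stage = spec$stages,
                   vintage = spec$vintages, vineyard = spec$vineyards,
                   stringsAsFactors = FALSE)
  g <- g[, c("vineyard", "vintage", "stage", "replicate")]
  rownames(g) <- sprintf("%s_%d_s%d_r%d", g$vineyard, g$vintage, g$stage,
                         g$replicate)
  studyDesign(g)
}

#' Generate a synthetic metabolome table
#'
#' Draws the log-scale model
#' \code{x = baseline + stage + vintage + macrozone + vineyard + noise},
#' exponentiates to positive intensities and applies per-sample dilution.
#' Every drawn effect is stored in the truth record, so recovery tests can
#' query the planted structure instead of re-deriving it.
#'
#' @param spec a [syntheticSpec()]
#' @return list with \code{table} (a raw \linkS4class{FeatureTable} with the
#'   design in \code{colData}), \code{design}, and \code{truth} (per-factor
#'   effect matrices, carrier masks, dilution factors, marker-group map)
#' @export
generateMetabolome <- function(spec = syntheticSpec()) {
  .withSeed(spec$seed, .generateMetabolome(spec))
}

.generateMetabolome <- function(spec) {
  design <- generateDesign(spec)
  n <- nrow(design); p <- spec$nFeatures
  featIDs <- sprintf("F%03d", seq_len(p))
  baseline <- rnorm(p, spec$baselineMean, spec$baselineSd)

  # chemical-class-like groups with per-feature loadings; climate (vintage)
  # and the shared part of the site effect act on group activities, so their
  # variation occupies the same feature-space directions — the correlated
  # structure that lets an unconstrained model confound the two
  groupOf <- sample.int(spec$nGroups, p, replace = TRUE)
  loading <- rnorm(p, 1, spec$loadingSd)
  macrozones <- unique(unname(.VINEYARD_MACROZONE[spec$vineyards]))
  actVintage <- matrix(rnorm(spec$nGroups * length(spec$vintages), 0,
                             spec$vintageSd),
                       spec$nGroups, length(spec$vintages),
                       dimnames = list(NULL, as.character(spec$vintages)))
  actMacro <- matrix(rnorm(spec$nGroups * length(macrozones), 0,
                           spec$macrozoneSd),
                     spec$nGroups, length(macrozones),
                     dimnames = list(NULL, macrozones))
  vintCarriers <- runif(p) < spec$vintageFrac
  macroCarriers <- runif(p) < spec$macrozoneFrac
  vinyCarriers <- runif(p) < spec$vineyardFrac
  # per-(feature, level) effect matrices on the log scale
  vintEff <- t(actVintage[groupOf, , drop = FALSE] * loading)
  vintEff[, !vintCarriers] <- 0
  dimnames(vintEff) <- list(as.character(spec$vintages), featIDs)
  macroShared <- t(actMacro[groupOf, , drop = FALSE] * loading)
  macroShared[, !macroCarriers] <- 0
  macroOwn <- matrix(rnorm(length(macrozones) * p, 0,
                           spec$macrozoneFeatureSd), length(macrozones), p)
  macroOwn[, !macroCarriers] <- 0
  macroEff <- macroShared + macroOwn
  dimnames(macroEff) <- list(macrozones, featIDs)
  vinyEff <- matrix(rnorm(length(spec$vineyards) * p, 0, spec$vineyardSd),
                    length(spec$vineyards), p,
                    dimnames = list(spec$vineyards, featIDs))
  vinyEff[, !vinyCarriers] <- 0
  # monotone stage trend with random sign per feature
  stageCarriers <- runif(p) < spec$stageFrac
  slope <- abs(rnorm(p, 0, spec$stageSd)) * sample(c(-1, 1), p, TRUE)
  slope[!stageCarriers] <- 0
  stageIdx <- match(design$stage, spec$stages)
  stageEffect <- outer(stageIdx - mean(seq_along(spec$stages)), slope)

  vint <- list(effects = vintEff, carriers = vintCarriers)
  macro <- list(effects = macroEff, carriers = macroCarriers)
  viny <- list(effects = vinyEff, carriers = vinyCarriers)

  logX <- matrix(baseline, n, p, byrow = TRUE) +
    stageEffect +
    vint$effects[as.character(design$vintage), , drop = FALSE] +
    macro$effects[design$macrozone, , drop = FALSE] +
    viny$effects[design$vineyard, , drop = FALSE] +
    matrix(rnorm(n * p, 0, spec$noiseSd), n, p)

  annotation <- data.frame(
    chemical_class = paste0("class", groupOf),
    marker_group = rep(NA_character_, p),
    row.names = featIDs)
  groupMap <- character(0)
  if (!is.null(spec$markerGroups)) {
    free <- seq_len(p)
    for (g in names(spec$markerGroups)) {
      mg <- spec$markerGroups[[g]]
      pick <- free[seq_len(mg$nFeatures)]
      free <- setdiff(free, pick)
      logX[design$macrozone == mg$macrozone, pick] <-
        logX[design$macrozone == mg$macrozone, pick] + mg$logFC
      annotation$marker_group[pick] <- g
      groupMap <- c(groupMap, setNames(rep(g, length(pick)),
                                       featIDs[pick]))
    }
  }

  dil <- if (spec$dilution)
    exp(runif(n, log(spec$dilutionRange[1L]), log(spec$dilutionRange[2L])))
  else rep(1, n)
  values <- exp(logX) * dil
  dimnames(values) <- list(rownames(design), featIDs)

  truth <- list(baseline = setNames(baseline, featIDs),
                group = setNames(groupOf, featIDs),
                loading = setNames(loading, featIDs),
                stageSlope = setNames(slope, featIDs),
                stageCarriers = setNames(stageCarriers, featIDs),
                vintage = vint, macrozone = macro, vineyard = viny,
                dilution = setNames(dil, rownames(design)),
                markerGroups = groupMap,
                logSignal = logX)
  list(table = FeatureTable(values, design = design,
                            annotation = annotation),
       design = design, truth = truth)
}

#' Ready-made confounded scenarios
#'
#' Presets for the headline experimental conditions:
#' \describe{
#'   \item{strong_vintage}{vintage effect sd three times the macrozone
#'     effect sd (the default, confounded regime)}
#'   \item{no_vintage}{no vintage effect at all}
#'   \item{null}{no structure: every factor effect sd is zero}
#' }
#'
#' @param preset one of \code{"strong_vintage"}, \code{"no_vintage"},
#'   \code{"null"}
#' @param seed generator seed
#' @param ... further overrides passed to [syntheticSpec()]
#' @return as [generateMetabolome()], plus \code{X} (the raw intensity
#'   matrix)
#' @export
confoundedScenario <- function(preset = c("strong_vintage", "no_vintage",
                                          "null"),
                               seed = NULL, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    strong_vintage = list(),
    no_vintage = list(vintageSd = 0),
    null = list(stageSd = 0, vintageSd = 0, macrozoneSd = 0,
                macrozoneFeatureSd = 0, vineyardSd = 0))
  spec <- do.call(syntheticSpec, c(args, list(seed = seed), list(...)))
  out <- generateMetabolome(spec)
  out$X <- intensities(out$table)
  out$spec <- spec
  out
}
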