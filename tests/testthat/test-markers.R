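fittedPT <- function(seed = 400, nFeatures = 40) {
  sc <- smallScenario(seed = seed, nFeatures = nFeatures)
  X <- lcmsChain(sc$table)
  m <- fitOCPLSDA(X, sc$design$macrozone, sc$design$vintage, A = 3)
  list(pt = postTransform(m, sc$design$macrozone), X = X,
       labels = sc$design$macrozone, sc = sc)
}

test_that("correlation loadings equal a direct per-pair Pearson oracle", {
  f <- fittedPT()
  pq <- correlationLoadings(f$pt, f$X, f$labels)
  Tm <- scores(f$pt)
  for (j in seq_len(ncol(f$X))) for (a in seq_len(ncol(Tm)))
    expect_equal(pq$pCorr[j, a], cor(f$X[, j], Tm[, a]), tolerance = 1e-12)
  Yc <- scale(dummyCode(f$labels)@Y, scale = FALSE)
  for (k in 1:3) for (a in seq_len(ncol(Tm)))
    expect_equal(pq$qCorr[k, a], cor(Yc[, k], Tm[, a]), tolerance = 1e-12)
  expect_true(all(abs(pq$pCorr) <= 1 + 1e-12, na.rm = TRUE))
})

test_that("a feature equal to a score has pq(corr) 1; orthogonal features 0", {
  f <- fittedPT()
  X2 <- cbind(f$X, tscore = scores(f$pt)[, 1])
  # orthogonalise one column against both predictive scores
  Tm <- scores(f$pt)
  v <- as.numeric(f$X[, 3] -
                    Tm %*% solve(crossprod(Tm), crossprod(Tm, f$X[, 3])))
  X2 <- cbind(X2, ortho = v)
  pq <- correlationLoadings(f$pt, X2, f$labels)
  expect_equal(unname(pq$pCorr["tscore", 1]), 1, tolerance = 1e-10)
  expect_lt(max(abs(pq$pCorr["ortho", ])), 1e-10)
})

test_that("zero-variance features are flagged, not fatal", {
  f <- fittedPT()
  X2 <- cbind(f$X, flat = 0)
  pq <- correlationLoadings(f$pt, X2, f$labels)
  expect_true(all(is.na(pq$pCorr["flat", ])))
  expect_identical(attr(pq, "flagged"), "flat")
})

test_that("marker extraction respects threshold, sign rule and monotonicity", {
  f <- fittedPT()
  pq <- correlationLoadings(f$pt, f$X, f$labels)
  mk50 <- extractMarkers(pq, threshold = 0.5)
  mk75 <- extractMarkers(pq, threshold = 0.75)
  # monotone: raising the threshold never adds markers
  expect_true(all(mk75$feature %in% mk50$feature))
  expect_lte(nrow(mk75), nrow(mk50))
  # sign rule: flipping a feature's loadings flips its sign, not its class
  if (nrow(mk50)) {
    j <- mk50$feature[1]
    pq2 <- pq
    pq2$pCorr[j, ] <- -pq2$pCorr[j, ]
    mk2 <- extractMarkers(pq2, threshold = 0.5)
    row1 <- mk50[mk50$feature == j, ]
    row2 <- mk2[mk2$feature == j, ]
    expect_identical(row2$class, row1$class)
    expect_false(identical(row2$sign, row1$sign))
  }
  expect_error(extractMarkers(pq, threshold = 1.01), "threshold")
  expect_error(extractMarkers(pq, threshold = 0), "threshold")
})

test_that("pq(corr) is invariant to positive feature scaling", {
  f <- fittedPT()
  Xs <- f$X
  Xs[, 1] <- 37 * Xs[, 1]
  pq1 <- correlationLoadings(f$pt, f$X, f$labels)
  pq2 <- correlationLoadings(f$pt, Xs, f$labels)
  expect_equal(pq2$pCorr[1, ], pq1$pCorr[1, ], tolerance = 1e-12)
})

test_that("marker-group aggregation averages member features over
           vineyard x vintage cells", {
  # one group, one feature, two replicates in one cell: mean of {2, 4} = 3
  design <- studyDesign(data.frame(
    vineyard = c("BA", "BA"), vintage = c(2006, 2006), stage = c(3, 3),
    replicate = c(1, 2)))
  rownames(design) <- c("r1", "r2")
  m <- matrix(c(2, 4), 2, 1, dimnames = list(c("r1", "r2"), "f1"))
  markers <- data.frame(feature = "f1", marker_group = "G1")
  agg <- aggregateMarkerGroups(m, markers, design)
  expect_equal(agg$value, 3)
  expect_identical(agg$group, "G1")
})

test_that("a planted elevated group dominates its macrozone in every
           vintage", {
  sc <- confoundedScenario(
    "strong_vintage", seed = 410, nFeatures = 60,
    markerGroups = list(ST1 = list(nFeatures = 5, macrozone = "LakeGarda",
                                   logFC = log(2))))
  norm <- medianFoldChangeNormalize(sc$table)$table
  groups <- sc$truth$markerGroups
  agg <- aggregateMarkerGroups(norm, NULL, sc$design, groups = groups)
  design <- sc$design
  lakeGarda <- unique(design$vineyard[design$macrozone == "LakeGarda"])
  for (v in unique(design$vintage)) {
    sub <- agg[agg$vintage == v, ]
    inLG <- sub$value[sub$vineyard %in% lakeGarda]
    outLG <- sub$value[!sub$vineyard %in% lakeGarda]
    expect_gt(min(inLG), max(outLG))
  }
})

test_that("empty marker groups are omitted with a warning", {
  design <- studyDesign(data.frame(vineyard = "BA", vintage = 2006,
                                   stage = 3, replicate = 1))
  rownames(design) <- "r1"
  m <- matrix(1, 1, 1, dimnames = list("r1", "f1"))
  expect_warning(
    agg <- aggregateMarkerGroups(m, NULL, design,
                                 groups = c(zz = "GHOST")),
    "GHOST")
  expect_identical(nrow(agg), 0L)
})
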