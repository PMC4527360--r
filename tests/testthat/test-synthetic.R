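test_that("the default design is the full 7 x 3 x 3 x 3 factorial", {
  d <- generateDesign(syntheticSpec())
  expect_identical(nrow(d), 189L)
  expect_identical(length(unique(d$vineyard)), 7L)
  expect_identical(length(unique(d$macrozone)), 3L)
  expect_identical(sort(unique(d$vintage)), c(2006L, 2007L, 2008L))
  # GC-MS-like preset: fully mature stage only
  dg <- generateDesign(syntheticSpec(nFeatures = 48, stages = 3L))
  expect_identical(nrow(dg), 63L)
  # single replicate pool
  d1 <- generateDesign(syntheticSpec(replicates = 1L))
  expect_identical(nrow(d1), 63L)
})

test_that("generation is seed-reproducible, bitwise", {
  a <- generateMetabolome(syntheticSpec(nFeatures = 30, seed = 500))
  b <- generateMetabolome(syntheticSpec(nFeatures = 30, seed = 500))
  expect_identical(intensities(a$table), intensities(b$table))
  expect_identical(a$truth$dilution, b$truth$dilution)
  c <- generateMetabolome(syntheticSpec(nFeatures = 30, seed = 501))
  expect_false(identical(intensities(a$table), intensities(c$table)))
})

test_that("all generated intensities are positive and effects are queryable", {
  gen <- generateMetabolome(syntheticSpec(nFeatures = 40, seed = 510))
  expect_gt(min(intensities(gen$table)), 0)
  tr <- gen$truth
  expect_named(tr$vintage, c("effects", "carriers"))
  expect_identical(dim(tr$vintage$effects), c(3L, 40L))
  expect_identical(dim(tr$macrozone$effects), c(3L, 40L))
  expect_identical(dim(tr$vineyard$effects), c(7L, 40L))
  # non-carriers have exactly zero planted effect
  expect_true(all(tr$vintage$effects[, !tr$vintage$carriers] == 0))
})

test_that("zero effect sds with dilution off give identical samples per
           baseline", {
  spec <- syntheticSpec(nFeatures = 20, stageSd = 0, vintageSd = 0,
                        macrozoneSd = 0, macrozoneFeatureSd = 0,
                        vineyardSd = 0, noiseSd = 0, dilution = FALSE,
                        seed = 520)
  gen <- generateMetabolome(spec)
  m <- intensities(gen$table)
  expect_lt(max(abs(sweep(m, 2, exp(gen$truth$baseline), "-"))), 1e-10)
})

test_that("planted dilution is removed by MFC normalization", {
  spec <- syntheticSpec(nFeatures = 25, noiseSd = 0, stageSd = 0,
                        vintageSd = 0, macrozoneSd = 0,
                        macrozoneFeatureSd = 0, vineyardSd = 0,
                        dilution = TRUE, seed = 530)
  gen <- generateMetabolome(spec)
  norm <- medianFoldChangeNormalize(gen$table)
  m <- intensities(norm$table)
  expect_lt(max(abs(sweep(m, 2, m[1, ], "-"))), 1e-8)
  # recovered factors proportional to the planted dilution
  f <- norm$factors / gen$truth$dilution
  expect_lt(diff(range(f)), 1e-10)
})

test_that("a vintage-carrying feature shows the planted variance share", {
  spec <- syntheticSpec(nFeatures = 60, seed = 540, dilution = FALSE)
  gen <- generateMetabolome(spec)
  tr <- gen$truth
  j <- which(tr$vintage$carriers &
             abs(tr$loading) > 0.8)[1]
  y <- log(intensities(gen$table)[, j])
  design <- gen$design
  # expected share from the truth record
  effs <- tr$vintage$effects[as.character(design$vintage), j]
  fit <- summary(aov(y ~ factor(design$vintage)))[[1]]
  ssShare <- fit[["Sum Sq"]][1] / sum(fit[["Sum Sq"]])
  truthShare <- var(effs) / var(y)
  expect_lt(abs(ssShare - truthShare), 0.15)
})

test_that("the strong-vintage preset clusters by vintage in PCA score space", {
  sc <- confoundedScenario("strong_vintage", seed = 550)
  X <- lcmsChain(sc$table)
  pc <- fitPCA(X, 2)
  sil <- function(labels, S) {
    D <- as.matrix(dist(S))
    mean(vapply(seq_len(nrow(S)), function(i) {
      # mean distance to own class (excluding self; D[i, i] = 0)
      a <- sum(D[i, labels == labels[i]]) / (sum(labels == labels[i]) - 1)
      b <- min(tapply(D[i, ], labels, mean)[
        setdiff(unique(labels), labels[i])])
      (b - a) / max(a, b)
    }, numeric(1)))
  }
  sVint <- sil(as.character(sc$design$vintage), scores(pc))
  sMz <- sil(sc$design$macrozone, scores(pc))
  expect_gt(sVint, sMz)
})

test_that("the null preset carries no class signal past a permutation test", {
  passes <- 0
  for (s in 1:10) {
    sc <- confoundedScenario("null", seed = 560 + s, nFeatures = 30)
    rec <- plsRecipe()
    perm <- permutationTest(rec, sc$X, sc$design$macrozone, A = 1,
                            nPerm = 19, seed = 560 + s)
    if (perm$passed) passes <- passes + 1
  }
  expect_lte(passes, 1)
})

test_that("unknown presets and invalid specs are rejected", {
  expect_error(confoundedScenario("banana"), "arg")
  expect_error(syntheticSpec(noiseSd = -1), ">= 0")
  expect_error(syntheticSpec(vintageFrac = 1.2), "\\[0, 1\\]")
  expect_error(syntheticSpec(vineyards = c("BA", "XX")), "XX")
})
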