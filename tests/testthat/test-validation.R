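test_that("fold assignment is a stratified partition", {
  lab <- threeClasses(27)
  for (nf in c(6, 7, 8)) {
    f <- cvFolds(lab, nf)
    expect_identical(sort(unique(f)), seq_len(nf))
    expect_identical(length(f), 27L)
    # every sample held out exactly once; folds near-balanced
    expect_lte(diff(range(table(f))), 1)
  }
  # seeded shuffle is deterministic and stays stratified
  f1 <- cvFolds(lab, 7, seed = 5)
  f2 <- cvFolds(lab, 7, seed = 5)
  expect_identical(f1, f2)
  expect_error(cvFolds(lab, 1), "at least 2")
})

test_that("a noiseless linear relation gives Q2 near 1", {
  set.seed(180)
  n <- 12
  lab <- rep(c("a", "b"), each = 6)
  yc <- ifelse(lab == "a", 1, -1)
  X <- outer(yc, rnorm(5)) + matrix(rnorm(n * 5, 0, 1e-6), n, 5)
  dimnames(X) <- list(paste0("s", 1:n), paste0("f", 1:5))
  rec <- modelRecipe("plsda", scaling = "center")
  expect_gt(crossvalQ2(rec, X, lab, A = 1, nFolds = 6), 0.99)
})

test_that("irrelevant predictors give non-positive Q2 in most seeds", {
  rec <- modelRecipe("plsda", scaling = "center")
  bad <- 0
  for (s in 1:10) {
    set.seed(190 + s)
    X <- matrix(rnorm(30 * 8), 30, 8,
                dimnames = list(paste0("s", 1:30), paste0("f", 1:8)))
    lab <- sample(rep(c("a", "b", "c"), 10))
    q2 <- crossvalQ2(rec, X, lab, A = 2, nFolds = 7, seed = s)
    if (q2 > 0) bad <- bad + 1
  }
  expect_lte(bad, 1)
})

test_that("full CV equals a hand-rolled two-split refit oracle", {
  set.seed(200)
  n <- 8
  lab <- rep(c("a", "b"), 4)
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(paste0("s", 1:n), paste0("f", 1:4)))
  rec <- modelRecipe("plsda", scaling = "center")
  q2 <- crossvalQ2(rec, X, lab, A = 1, nFolds = 2)
  # oracle: explicit refit loop over the same deterministic folds
  folds <- cvFolds(lab, 2)
  classes <- unique(lab)
  press <- 0; ss <- 0
  for (k in 1:2) {
    tr <- which(folds != k); te <- which(folds == k)
    mu <- colMeans(X[tr, ])
    Xtr <- sweep(X[tr, ], 2, mu); Xte <- sweep(X[te, ], 2, mu)
    Ytr <- dummyCode(factor(lab[tr], levels = classes))
    fit <- fitPLSDA(Xtr, Ytr, A = 1)
    Yhat <- predict(fit, Xte)
    Yte <- dummyCode(factor(lab[te], levels = classes))@Y
    press <- press + sum((Yte - Yhat)^2)
    ss <- ss + sum(sweep(Yte, 2, colMeans(Ytr@Y))^2)
  }
  expect_identical(q2, 1 - press / ss)   # bitwise on PRESS/SS terms
})

test_that("Q2 equals R2 when every training fold reproduces the full model", {
  # single informative feature, deterministic relation: every fold fits the
  # same coefficient, so cross-validated and fitted residuals coincide
  lab <- rep(c("a", "b"), each = 6)
  x <- ifelse(lab == "a", 1, -1)
  X <- matrix(x, 12, 1, dimnames = list(paste0("s", 1:12), "f1"))
  rec <- modelRecipe("plsda", scaling = "none")
  q2 <- crossvalQ2(rec, X, lab, A = 1, nFolds = 6)
  m <- fitPLSDA(sweep(X, 2, colMeans(X)), lab, A = 1)
  r2 <- r2y(m, sweep(X, 2, colMeans(X)), lab)
  expect_equal(q2, r2, tolerance = 1e-12)
})

test_that("losing a whole class from a fold is refused", {
  lab <- c(rep("a", 10), "b")
  X <- matrix(rnorm(22), 11, 2,
              dimnames = list(paste0("s", 1:11), c("f1", "f2")))
  rec <- modelRecipe("plsda", scaling = "center")
  expect_error(crossvalQ2(rec, X, lab, A = 1, nFolds = 2), "class 'b'")
})

test_that("permutation test: strong signal gives the minimal p-value", {
  set.seed(210)
  n <- 18
  lab <- rep(c("a", "b"), each = 9)
  yc <- ifelse(lab == "a", 1, -1)
  X <- outer(yc, rnorm(6)) + matrix(rnorm(n * 6, 0, 0.05), n, 6)
  dimnames(X) <- list(paste0("s", 1:n), paste0("f", 1:6))
  rec <- modelRecipe("plsda", scaling = "center")
  perm <- permutationTest(rec, X, lab, A = 1, nPerm = 99, seed = 211)
  expect_equal(perm$pValue, 1 / 100)
  expect_true(perm$passed)
  expect_identical(length(perm$nullQ2), 99L)
  # observed Q2 exceeds every permuted Q2 (explicit-loop oracle for p)
  expect_identical(perm$pValue,
                   (1 + sum(perm$nullQ2 >= perm$observedQ2)) / 100)
  expect_error(permutationTest(rec, X, lab, A = 1, nPerm = 0), "at least 1")
})

test_that("pure-noise X rarely passes the permutation test", {
  rec <- modelRecipe("plsda", scaling = "center")
  passes <- 0
  for (s in 1:10) {
    set.seed(220 + s)
    X <- matrix(rnorm(24 * 6), 24, 6,
                dimnames = list(paste0("s", 1:24), paste0("f", 1:6)))
    lab <- rep(c("a", "b"), 12)
    perm <- permutationTest(rec, X, lab, A = 1, nPerm = 39, seed = 220 + s)
    if (perm$passed) passes <- passes + 1
  }
  expect_lte(passes, 1)
})

test_that("component selection takes the first local maximum of Q2", {
  expect_identical(terroirPLS:::.firstMaximum(c(0.40, 0.60, 0.55)), 2L)
  expect_identical(terroirPLS:::.firstMaximum(c(0.1, 0.2, 0.3)), 3L)
  expect_identical(terroirPLS:::.firstMaximum(0.5), 1L)
  expect_identical(terroirPLS:::.firstMaximum(c(0.7, 0.2, 0.9)), 1L)
})

test_that("selectComponents accepts real structure and rejects noise", {
  sc <- smallScenario(seed = 230, nFeatures = 50)
  rec <- ocplsRecipe(sc$design$vintage)
  rep <- selectComponents(rec, sc$X, sc$design$macrozone, maxA = 4,
                          nPerm = 39, seed = 231)
  expect_identical(rep@status, "accepted")
  expect_gte(rep@selectedA, 1L)
  expect_gt(rep@q2ByScheme[[1]], 0.5)
  # pure noise: rejected
  set.seed(232)
  Xn <- matrix(rnorm(30 * 10), 30, 10,
               dimnames = list(paste0("s", 1:30), paste0("f", 1:10)))
  labn <- sample(rep(c("a", "b", "c"), 10))
  recn <- modelRecipe("plsda", scaling = "center")
  repn <- selectComponents(recn, Xn, labn, maxA = 2, nPerm = 39, seed = 233)
  expect_identical(repn@status, "rejected")
  expect_true(is.na(repn@selectedA))
})

test_that("strictly increasing Q2 warns and selects maxA", {
  set.seed(240)
  n <- 24
  lab <- rep(c("a", "b"), each = 12)
  yc <- ifelse(lab == "a", 1, -1)
  # two informative directions of decreasing strength keep Q2 rising
  X <- outer(yc, c(rnorm(4), rep(0, 4))) +
    outer(rep(c(1, -1), 12), c(rep(0, 4), rnorm(4)) * 0.5) +
    matrix(rnorm(n * 8, 0, 0.3), n, 8)
  dimnames(X) <- list(paste0("s", 1:n), paste0("f", 1:8))
  rec <- modelRecipe("plsda", scaling = "center")
  q2s <- vapply(1:2, function(a) crossvalQ2(rec, X, lab, a, 7), numeric(1))
  if (diff(q2s) > 0)
    expect_warning(selectComponents(rec, X, lab, maxA = 2, nPerm = 19,
                                    seed = 241),
                   "increasing")
  else succeed()
})

test_that("r2y matches the between/total decomposition for a class-means
           predictor", {
  set.seed(250)
  lab <- rep(c("a", "b", "c"), each = 5)
  X <- dummyCode(lab)@Y + matrix(rnorm(45, 0, 1e-8), 15, 3)
  dimnames(X) <- list(paste0("s", 1:15), paste0("f", 1:3))
  Xc <- sweep(X, 2, colMeans(X))
  m <- fitPLSDA(Xc, lab, A = 2)
  # predicting the class means: R2Y = between-class / total Y variance = 1
  # here because Y is exactly the class indicator
  expect_equal(r2y(m, Xc, lab), 1, tolerance = 1e-6)
  expect_error(r2y(m, Xc, rep("a", 15)), ">=2 classes")
})

test_that("validateModel reports all fold schemes and the permutation record", {
  sc <- smallScenario(seed = 260, nFeatures = 40)
  rec <- ocplsRecipe(sc$design$vintage)
  rep <- validateModel(rec, sc$X, sc$design$macrozone, A = 2,
                       foldSchemes = c(6L, 7L, 8L), nPerm = 19, seed = 261)
  expect_named(rep@q2ByScheme, c("6", "7", "8"))
  expect_true(all(rep@q2ByScheme <= 1))
  expect_gt(rep@r2y, 0.5)
  expect_identical(rep@permutation$nPerm, 19L)
})
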