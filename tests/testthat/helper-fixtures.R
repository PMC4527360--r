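# shared fixtures: everything built in code, no files on disk

# centered random matrix with dimnames
randCentered <- function(n, p, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("f", seq_len(p))))
  sweep(m, 2L, colMeans(m), "-")
}

# positive intensity matrix with dimnames
randPositive <- function(n, p, seed = 1) {
  set.seed(seed)
  matrix(exp(rnorm(n * p, 5, 1)), n, p,
         dimnames = list(paste0("s", seq_len(n)), paste0("f", seq_len(p))))
}

# small three-class labels, balanced
threeClasses <- function(n) rep(c("LakeGarda", "Valpolicella", "Soave"),
                                length.out = n)

# a small strong-vintage scenario for fast model tests
smallScenario <- function(seed = 1, nFeatures = 60L, ...) {
  confoundedScenario("strong_vintage", seed = seed, nFeatures = nFeatures,
                     ...)
}

# the standard LC-MS-like preprocessing recipe pair used in several tests
ocplsRecipe <- function(constraintLabels)
  modelRecipe("ocplsda", scaling = "center", mfc = TRUE, log = TRUE,
              constraintLabels = constraintLabels)

plsRecipe <- function()
  modelRecipe("plsda", scaling = "center", mfc = TRUE, log = TRUE)

# preprocess a raw table with the LC-MS chain and return the centered matrix
lcmsChain <- function(table) {
  lg <- logTransform(medianFoldChangeNormalize(table)$table)
  intensities(meanCenter(lg)$table)
}

expect_equal_upto_sign <- function(A, B, tol = 1e-8) {
  expect_equal(dim(A), dim(B))
  for (j in seq_len(ncol(A))) {
    d <- min(max(abs(A[, j] - B[, j])), max(abs(A[, j] + B[, j])))
    expect_lt(d, tol)
  }
}
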