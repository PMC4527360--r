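test_that("internal-standard normalization divides by the assigned IS area", {
  m <- matrix(c(100, 80, 60, 40, 20, 10), 1, 6,
              dimnames = list("s1", paste0("f", 1:6)))
  ann <- data.frame(
    internal_standard_key = c("alpha-copaene", "alpha-copaene",
                              "d3-b-ionone", "d13-hexanol", "d13-hexanol",
                              "none"),
    row.names = paste0("f", 1:6))
  isAreas <- matrix(c(50, 10, 4), 1, 3,
                    dimnames = list("s1", c("alpha-copaene", "d3-b-ionone",
                                            "d13-hexanol")))
  out <- internalStandardNormalize(FeatureTable(m), ann, isAreas)
  # sesquiterpene-style feature: area 100 over alpha-copaene 50 -> 2.0
  expect_equal(unname(intensities(out)[1, ]), c(2, 1.6, 6, 10, 5, 10))
  expect_identical(tableState(out), "normalized")
})

test_that("IS normalization matches a per-cell loop oracle and commutes with
           feature reordering", {
  set.seed(42)
  m <- randPositive(4, 6, seed = 42)
  keys <- sample(c("alpha-copaene", "d3-b-ionone", "d13-hexanol"), 6, TRUE)
  ann <- data.frame(internal_standard_key = keys, row.names = colnames(m))
  isAreas <- matrix(runif(12, 1, 5), 4, 3,
                    dimnames = list(rownames(m),
                                    c("alpha-copaene", "d3-b-ionone",
                                      "d13-hexanol")))
  out <- intensities(internalStandardNormalize(FeatureTable(m), ann, isAreas))
  oracle <- m
  for (i in 1:4) for (j in 1:6) oracle[i, j] <- m[i, j] / isAreas[i, keys[j]]
  expect_equal(out, oracle, tolerance = 1e-14)
  # commutes with feature reordering
  ord <- sample(6)
  out2 <- intensities(internalStandardNormalize(
    FeatureTable(m[, ord]), ann[ord, , drop = FALSE], isAreas))
  expect_equal(out2, out[, ord], tolerance = 1e-14)
  # identity when all areas are 1
  ones <- matrix(1, 4, 3, dimnames = dimnames(isAreas))
  expect_equal(intensities(internalStandardNormalize(FeatureTable(m), ann,
                                                     ones)),
               m)
  # zero IS area names sample and standard
  bad <- isAreas; bad[2, "d3-b-ionone"] <- 0
  expect_error(internalStandardNormalize(FeatureTable(m), ann, bad),
               "d3-b-ionone.*s2")
})

test_that("median fold change normalization matches the median-of-ratios
           oracle and removes pure dilution", {
  m <- randPositive(5, 10, seed = 9)
  res <- medianFoldChangeNormalize(FeatureTable(m))
  ref <- apply(m, 2, median)
  oracleFactors <- apply(m, 1, function(x) median(x / ref))
  expect_equal(unname(res$factors), unname(oracleFactors), tolerance = 1e-14)
  expect_equal(intensities(res$table), m / oracleFactors, tolerance = 1e-14)
  # sample B = 2 x sample A: factors ratio 2, normalized rows equal
  two <- rbind(A = m[1, ], B = 2 * m[1, ])
  colnames(two) <- colnames(m)
  r2 <- medianFoldChangeNormalize(FeatureTable(two))
  expect_equal(unname(r2$factors[["B"]] / r2$factors[["A"]]), 2)
  expect_equal(intensities(r2$table)[1, ], intensities(r2$table)[2, ],
               tolerance = 1e-12)
  # single sample: factor 1
  one <- m[1, , drop = FALSE]
  expect_equal(unname(medianFoldChangeNormalize(FeatureTable(one))$factors),
               1)
})

test_that("renormalizing against the stored reference yields unit factors", {
  m <- randPositive(6, 12, seed = 10)
  first <- medianFoldChangeNormalize(FeatureTable(m))
  again <- medianFoldChangeNormalize(first$table,
                                     reference = first$reference)
  expect_lt(max(abs(again$factors - 1)), 1e-10)
})

test_that("log transform is the documented shifted natural log", {
  m <- matrix(c(0, exp(1) - 1), 2, 1, dimnames = list(c("s1", "s2"), "f1"))
  out <- intensities(logTransform(FeatureTable(m), epsilon = 1))
  expect_equal(unname(out[, 1]), c(0, 1))
  # monotone for any epsilon
  x <- sort(runif(20, 0, 100))
  ft <- FeatureTable(matrix(x, 20, 1,
                            dimnames = list(paste0("s", 1:20), "f1")))
  for (eps in c(0.01, 1, 10))
    expect_true(all(diff(intensities(logTransform(ft, eps))[, 1]) > 0))
  neg <- matrix(c(-1, 1), 2, 1, dimnames = list(c("s1", "s2"), "f1"))
  expect_error(FeatureTable(neg), "negative")
})

test_that("centering and autoscaling satisfy their column constraints and
           round-trip via stored parameters", {
  m <- randPositive(8, 5, seed = 11)
  lg <- logTransform(FeatureTable(m))
  cen <- meanCenter(lg)
  expect_lt(max(abs(colSums(intensities(cen$table)))), 1e-10)
  aut <- autoscale(lg)
  sds <- apply(intensities(aut$table), 2, sd)
  expect_lt(max(abs(sds - 1)), 1e-10)
  expect_lt(max(abs(colMeans(intensities(aut$table)))), 1e-10)
  # stored parameters reproduce the scaled table on the training data
  re <- applyScaling(intensities(lg), aut$means, aut$sds)
  expect_equal(re, intensities(aut$table), tolerance = 1e-12)
  # zero-variance feature under autoscale names the feature
  flat <- m; flat[, 2] <- 7
  expect_error(autoscale(logTransform(FeatureTable(flat))), "f2")
})

test_that("the LC-MS chain maps scalar multiples of one profile to zeros", {
  profile <- exp(rnorm(30, 5, 1))
  scal <- c(0.5, 1, 1.7, 2, 3.1, 0.8)
  m <- outer(scal, profile)
  dimnames(m) <- list(paste0("s", 1:6), paste0("f", 1:30))
  out <- lcmsChain(FeatureTable(m))
  expect_lt(max(abs(out)), 1e-8)
})

test_that("table state can only move forward", {
  m <- randPositive(4, 3, seed = 12)
  lg <- logTransform(FeatureTable(m))
  expect_error(medianFoldChangeNormalize(meanCenter(lg)$table),
               "backwards|>= 0")
})
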