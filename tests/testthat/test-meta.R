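# one-voxel grid for scalar worked examples
scalarGrid <- function() makeGrid(c(2, 1, 1), nNetworks = 2L)

test_that("the k = 3 hand-worked example is exact", {
  g <- scalarGrid()
  s <- summariesFrom(g, means = cbind(c(1, 2, 3), c(1, 2, 3)),
                     vars = matrix(1, 3, 2), ns = c(10, 10, 10))
  m <- randomEffectsMeta(s)
  expect_equal(m@q[1], 20, tolerance = 1e-10)
  expect_equal(m@df, 2L)
  expect_equal(m@tau2[1], 0.9, tolerance = 1e-10)
  expect_equal(m@i2[1], 90, tolerance = 1e-10)
  expect_equal(m@mStar[1], 2, tolerance = 1e-10)
  expect_equal(m@se[1], 1 / sqrt(3), tolerance = 1e-10)
  expect_equal(m@weightsOriginal[, 1], rep(10, 3))
  expect_equal(m@weightsUpdated[, 1], rep(1, 3), tolerance = 1e-10)
  # closed-form effect sizes: Z = 2*sqrt(3), d = 2
  expect_equal(m@z[1], 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(m@d[1], 2, tolerance = 1e-10)
})

test_that("identical cohorts collapse to the homogeneity limit", {
  g <- scalarGrid()
  s <- summariesFrom(g, means = matrix(1.5, 4, 2),
                     vars = matrix(2, 4, 2), ns = rep(8, 4))
  m <- randomEffectsMeta(s)
  expect_equal(m@q, rep(0, 2), tolerance = 1e-10)
  expect_equal(m@tau2, rep(0, 2))
  expect_equal(m@i2, rep(0, 2))
  expect_equal(m@mStar, rep(1.5, 2), tolerance = 1e-10)
  expect_equal(m@se, rep(sqrt(1 / (4 * 8 / 2)), 2), tolerance = 1e-10)
})

test_that("with tau2 = 0 the pooled mean is the fixed-effect mean", {
  g <- scalarGrid()
  means <- cbind(c(1.0, 1.01, 0.99), c(0.5, 0.52, 0.48))
  vars <- cbind(c(1, 2, 4), c(1, 2, 4)) * 1e4  # huge variance => Q < df
  s <- summariesFrom(g, means, vars, ns = c(10, 20, 40))
  m <- randomEffectsMeta(s)
  expect_equal(m@tau2, c(0, 0))
  W <- t(vapply(s, function(x) x@nSubjects / x@varianceMap, numeric(2)))
  expect_equal(m@mStar, colSums(W * means) / colSums(W),
               tolerance = 1e-12)
})

test_that("the voxelwise engine agrees with metafor's DL estimator", {
  skip_if_not_installed("metafor")
  g <- smallGrid(c(3, 3, 2), nNetworks = 2L)
  s <- nullCohortSummaries(g, k = 8L, n = 15L, seed = 3)
  m <- randomEffectsMeta(s)
  for (v in c(1L, 7L, 18L)) {
    rf <- metafor::rma(
      yi = vapply(s, function(x) x@meanMap[v], numeric(1)),
      vi = vapply(s, function(x) x@varianceMap[v] / x@nSubjects,
                  numeric(1)),
      method = "DL")
    expect_equal(m@mStar[v], as.numeric(rf$beta), tolerance = 1e-10)
    expect_equal(m@se[v], rf$se, tolerance = 1e-10)
    expect_equal(m@tau2[v], rf$tau2, tolerance = 1e-10)
    expect_equal(m@i2[v], rf$I2, tolerance = 1e-8)
    expect_equal(m@q[v], rf$QE, tolerance = 1e-10)
  }
})

test_that("scaling all cohort means scales M*, SE and sqrt(T2) alike", {
  g <- scalarGrid()
  set.seed(5)
  means <- matrix(rnorm(10, 1), 5, 2)
  vars <- matrix(runif(10, 0.5, 2), 5, 2)
  s1 <- summariesFrom(g, means, vars, ns = rep(12, 5))
  s2 <- summariesFrom(g, 3 * means, 9 * vars, ns = rep(12, 5))
  m1 <- randomEffectsMeta(s1)
  m2 <- randomEffectsMeta(s2)
  expect_equal(m2@mStar, 3 * m1@mStar, tolerance = 1e-10)
  expect_equal(m2@se, 3 * m1@se, tolerance = 1e-10)
  expect_equal(sqrt(m2@tau2), 3 * sqrt(m1@tau2), tolerance = 1e-10)
  expect_equal(m2@i2, m1@i2, tolerance = 1e-10)
  expect_equal(m2@z, m1@z, tolerance = 1e-10)
  expect_equal(m2@d, m1@d, tolerance = 1e-10)
})

test_that("cohort order does not matter", {
  g <- scalarGrid()
  set.seed(6)
  means <- matrix(rnorm(8), 4, 2)
  vars <- matrix(runif(8, 0.5, 2), 4, 2)
  s <- summariesFrom(g, means, vars, ns = c(5, 9, 14, 22))
  m1 <- randomEffectsMeta(s)
  m2 <- randomEffectsMeta(s[c(3, 1, 4, 2)])
  for (sl in c("mStar", "se", "q", "tau2", "i2", "z", "d"))
    expect_equal(slot(m1, sl), slot(m2, sl), tolerance = 1e-12)
})

test_that("parameter recovery on simulated cohorts", {
  # voxel-averaged T2 near the generating tau2, and ~95% CI coverage
  g <- smallGrid(c(8, 8, 8), nNetworks = 2L)  # 512 simulated voxels
  tau2 <- 0.04
  truth <- makeGroundTruth(g, nHubs = 0L, tau2 = tau2, sigmaWithin = 1,
                           betaAge = 0, betaSex = 0, seed = 2)
  coh <- simulateCohortMaps(g, truth, rep(25, 60), seed = 13)
  m <- randomEffectsMeta(summarizeCohorts(coh, g))
  expect_lt(abs(mean(m@tau2) - tau2) / tau2, 0.15)
  cover <- mean(abs(m@mStar - truth@trueMeanMap) <= 1.96 * m@se)
  expect_gte(cover, 0.93)
  expect_lte(cover, 0.97)
})

test_that("degenerate inputs are guarded", {
  g <- scalarGrid()
  s <- summariesFrom(g, matrix(1, 1, 2), matrix(1, 1, 2), 5)
  expect_error(randomEffectsMeta(s), "insufficient cohorts")
  s2 <- summariesFrom(g, matrix(1, 2, 2), rbind(c(0, 1), c(1, 1)),
                      c(5, 5))
  expect_warning(m <- randomEffectsMeta(s2), "non-positive")
  expect_true(is.nan(m@mStar[1]))
  expect_false(is.nan(m@mStar[2]))
})
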