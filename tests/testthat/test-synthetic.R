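test_that("degenerate noise reproduces the true mean exactly", {
  g <- smallGrid()
  truth <- makeGroundTruth(g, nHubs = 1L, tau2 = 0, sigmaWithin = 1e-12,
                           betaAge = 0, betaSex = 0, seed = 2)
  coh <- simulateCohortMaps(g, truth, c(3, 4), seed = 5)
  for (ch in coh)
    expect_lt(max(abs(t(ch@maps) - truth@trueMeanMap)), 1e-9)
})

test_that("cohort simulation is deterministic and guards sizes", {
  g <- smallGrid()
  truth <- makeGroundTruth(g, seed = 2)
  a <- simulateCohortMaps(g, truth, c(4, 5), seed = 9)
  b <- simulateCohortMaps(g, truth, c(4, 5), seed = 9)
  expect_identical(lapply(a, slot, "maps"), lapply(b, slot, "maps"))
  expect_identical(a[[1]]@ages, b[[1]]@ages)
  expect_error(simulateCohortMaps(g, truth, c(4, 1), seed = 1), ">= 2")
})

test_that("between-cohort variance of cohort means matches tau2 + sigma2/N", {
  # law of total variance at each voxel, averaged over many cohorts
  g <- smallGrid(c(4, 4, 4))
  tau2 <- 0.04; sigma <- 1; n <- 10
  truth <- makeGroundTruth(g, nHubs = 0L, tau2 = tau2, sigmaWithin = sigma,
                           betaAge = 0, betaSex = 0, seed = 2)
  coh <- simulateCohortMaps(g, truth, rep(n, 500), seed = 31)
  cm <- t(vapply(coh, function(ch) colMeans(ch@maps),
                 numeric(nVoxels(g))))
  v <- apply(cm, 2L, var)
  expected <- tau2 + sigma^2 / n
  expect_lt(abs(mean(v) - expected) / expected, 0.1)
})

test_that("planted hubs are contiguous and carry the stated amplitude", {
  g <- makeGrid(c(10, 10, 10))
  truth <- makeGroundTruth(g, nHubs = 1L, hubRadiusMm = 6,
                           hubAmplitude = 0.5, seed = 7)
  expect_true(all(truth@trueMeanMap[truth@hubMaskTrue] >= 0.5))
  expect_true(all(truth@trueMeanMap[!truth@hubMaskTrue] == 0))
  # one 26-connected component
  comp <- metaHub:::.connectedComponents(g, which(truth@hubMaskTrue), 26L)
  expect_equal(length(unique(comp)), 1L)
})

test_that("time-series cohorts realize the planted correlation structure", {
  g <- smallGrid(c(4, 4, 3), nNetworks = 2L)
  nv <- nVoxels(g)
  blk <- 1:10
  ts <- simulateTimeseriesCohort(g, list(blocks = list(blk), r = 0.6),
                                 nTimepoints = 400, seed = 3)[[1]]
  R <- cor(ts)
  expect_gt(mean(R[blk, blk][upper.tri(diag(10))]), 0.5)
  off <- R[blk, setdiff(1:nv, blk)]
  expect_lt(mean(abs(off)), 0.1)
  # identity spec gives near-zero correlations
  ts0 <- simulateTimeseriesCohort(g, diag(nv), nTimepoints = 400,
                                  seed = 4)[[1]]
  R0 <- cor(ts0)
  expect_lt(mean(abs(R0[upper.tri(R0)])), 0.1)
  # planted block voxels have the highest brute-force FCS
  fcs <- mapValues(computeFcs(ts, g, FcsParams(0.1, 0, TRUE)))
  expect_setequal(order(-fcs)[1:10], blk)
  # determinism and the positive-definite guard
  ts2 <- simulateTimeseriesCohort(g, diag(nv), nTimepoints = 60, seed = 9)
  ts3 <- simulateTimeseriesCohort(g, diag(nv), nTimepoints = 60, seed = 9)
  expect_identical(ts2, ts3)
  badR <- matrix(1, nv, nv)
  badR[1, 2] <- badR[2, 1] <- -1
  expect_error(simulateTimeseriesCohort(g, badR, 60, 1),
               "positive definite")
})

test_that("expression simulation plants a recoverable signal", {
  g <- makeGrid(c(12, 12, 12))
  # with no effect, hub/non-hub rank-sum p values are uniform
  e0 <- simulateExpression(40, 60, 80, 20, effect = 0, grid = g, seed = 5)
  X <- exprValues(e0)
  hub <- sampleLabels(e0) == "hub"
  ps <- apply(X, 2L, function(v)
    wilcox.test(v[hub], v[!hub], exact = FALSE)$p.value)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
  # with a strong effect, informative genes top the standardized
  # mean-difference ranking on average over replicates
  hits <- vapply(1:50, function(r) {
    e <- simulateExpression(30, 40, 40, 8, effect = 1, grid = g,
                            seed = 100 + r)
    Xr <- exprValues(e)
    hb <- sampleLabels(e) == "hub"
    smd <- abs(apply(Xr, 2L, function(v)
      (mean(v[hb]) - mean(v[!hb])) / sd(v)))
    mean(order(-smd)[1:8] <= 8)
  }, numeric(1))
  expect_gt(mean(hits), 0.8)
  # determinism
  e1 <- simulateExpression(10, 12, 15, 5, grid = g, seed = 77)
  e2 <- simulateExpression(10, 12, 15, 5, grid = g, seed = 77)
  expect_identical(exprValues(e1), exprValues(e2))
  expect_error(simulateExpression(10, 12, 15, 30, grid = g, seed = 1),
               "exceed")
})
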