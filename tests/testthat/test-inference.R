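test_that("permutation p values respect the add-one bounds and ties", {
  g <- makeGrid(c(4, 1, 1), nNetworks = 2L)
  null <- new("PermutationNull", maxZ = as.numeric(1:10),
              nIterations = 10L, seed = 1L)
  z <- VoxelMap(g, c(99, -99, 5, 5))
  p <- mapValues(assignP(z, null))
  expect_equal(p[1], 1 / 11)          # above every null value
  expect_equal(p[2], 1)               # below every null value
  expect_equal(p[3], p[4])            # ties share a p value
  expect_equal(p[3], (1 + 6) / 11)    # #{null >= 5} = 6
  # monotone non-increasing in Z
  zz <- VoxelMap(g, c(0, 2, 4, 8))
  expect_true(all(diff(mapValues(assignP(zz, null))) <= 0))
})

test_that("the permutation null is reproducible and degenerate on one voxel", {
  g <- smallGrid(c(3, 3, 2), nNetworks = 2L)
  s <- nullCohortSummaries(g, k = 4L, n = 8L, seed = 5)
  n1 <- permutationNull(s, 50L, seed = 9)
  n2 <- permutationNull(s, 50L, seed = 9)
  expect_identical(n1@maxZ, n2@maxZ)
  # single-voxel grid: permutation is the identity, the null collapses
  g1 <- new("VoxelGrid", dims = c(1L, 1L, 1L), voxelSizeMm = 3,
            affine = diag(4), grayMask = array(TRUE, c(1, 1, 1)),
            networkLabels = array(1L, c(1, 1, 1)), maskIdx = 1L,
            coordsMm = matrix(0, 1, 3))
  s1 <- summariesFrom(g1, means = matrix(c(1, 1.2), 2, 1),
                      vars = matrix(1, 2, 1), ns = c(6, 6))
  m1 <- randomEffectsMeta(s1)
  null1 <- permutationNull(s1, 25L, seed = 2)
  expect_true(all(abs(null1@maxZ - m1@z[1]) < 1e-12))
})

test_that("cluster-extent thresholding applies the strict volume rule", {
  # 3-mm voxels: 8 voxels = 216 mm^3 survive, 7 voxels = 189 mm^3 do not
  g <- makeGrid(c(12, 6, 6), nNetworks = 2L)
  dims <- g@dims
  p <- rep(1, nVoxels(g))
  vox <- function(i, j, k) i + dims[1] * (j - 1L) + prod(dims[1:2]) * (k - 1L)
  blobA <- c(vox(2, 2, 2), vox(3, 2, 2), vox(2, 3, 2), vox(3, 3, 2),
             vox(2, 2, 3), vox(3, 2, 3), vox(2, 3, 3), vox(3, 3, 3))
  blobB <- c(vox(9, 2, 2), vox(10, 2, 2), vox(9, 3, 2), vox(10, 3, 2),
             vox(9, 2, 3), vox(10, 2, 3), vox(9, 3, 3))
  p[c(blobA, blobB)] <- 1e-4
  hr <- thresholdHubs(VoxelMap(g, p), VoxelMap(g, -log(p)),
                      alpha = 0.001, minClusterMm3 = 200, g)
  expect_equal(sum(hubMask(hr)), 8L)
  expect_setequal(which(hubMask(hr)), blobA)
  expect_equal(length(setdiff(unique(clusterLabels(hr)), 0L)), 1L)
  # nothing suprathreshold: empty mask is valid
  hr0 <- thresholdHubs(VoxelMap(g, rep(1, nVoxels(g))),
                       VoxelMap(g, rep(0, nVoxels(g))), 0.001, 200, g)
  expect_equal(sum(hubMask(hr0)), 0L)
  expect_equal(nrow(hubPeaks(extractPeaks(VoxelMap(g, rep(0, nVoxels(g))),
                                          hr0))), 0L)
})

test_that("peak extraction separates maxima by the distance rule", {
  # two equal-height maxima 12 mm apart -> one peak; 18 mm apart -> two
  g <- makeGrid(c(13, 5, 5), nNetworks = 2L)
  dims <- g@dims
  vox <- function(i, j, k) i + dims[1] * (j - 1L) + prod(dims[1:2]) * (k - 1L)
  mkcase <- function(sep) {
    z <- rep(0, nVoxels(g))
    p <- rep(1, nVoxels(g))
    line <- vapply(3:(3 + sep / 3), function(i) vox(i, 3, 3), numeric(1))
    z[line] <- 5
    z[line[1]] <- 10
    z[line[length(line)]] <- 10
    p[line] <- 1e-4
    hr <- thresholdHubs(VoxelMap(g, p), VoxelMap(g, z), 0.001, 0, g)
    hubPeaks(extractPeaks(VoxelMap(g, z), hr, minSeparationMm = 15))
  }
  expect_equal(nrow(mkcase(12)), 1L)
  pk <- mkcase(18)
  expect_equal(nrow(pk), 2L)
  expect_equal(abs(diff(pk$x)), 18)
})

test_that("a single blob with a unique maximum yields exactly one peak", {
  g <- makeGrid(c(9, 9, 9), nNetworks = 2L)
  truth <- makeGroundTruth(g, nHubs = 1L, hubRadiusMm = 7.5,
                           hubAmplitude = 1, seed = 3)
  z <- truth@trueMeanMap * 10
  p <- ifelse(truth@hubMaskTrue, 1e-4, 1)
  hr <- thresholdHubs(VoxelMap(g, p), VoxelMap(g, z), 0.001, 200, g)
  hr <- extractPeaks(VoxelMap(g, z), hr, 15)
  pk <- hubPeaks(hr)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$Z, max(z))
  # every peak lies inside its cluster; counts bounded by cluster size
  expect_true(all(pk$cluster %in% clusterLabels(hr)))
})

test_that("peaks carry the meta-analytic effect columns, sorted by d", {
  g <- smallGrid(c(8, 8, 8), nNetworks = 2L)
  truth <- makeGroundTruth(g, nHubs = 2L, hubRadiusMm = 6,
                           hubAmplitude = 1.2, tau2 = 0.01, seed = 8)
  coh <- simulateCohortMaps(g, truth, rep(15, 10), seed = 4)
  res <- identifyHubs(summarizeCohorts(coh, g), nPermutations = 999L,
                      alpha = 0.005, seed = 5)
  pk <- hubPeaks(res$hubs)
  expect_gt(nrow(pk), 0L)
  expect_true(all(diff(pk$d) <= 0))
  expect_equal(pk$d, pk$Z / sqrt(res$meta@k))
  # every hub voxel carries a cluster label (class validity holds)
  expect_true(validObject(res$hubs))
})
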