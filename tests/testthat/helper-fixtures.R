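# Shared fixtures, built in code at test time.

smallGrid <- function(dims = c(6, 6, 6), voxelSizeMm = 3, nNetworks = 4L,
                      seed = 1L) {
  makeGrid(dims, voxelSizeMm, nNetworks, seed)
}

# cohort summaries straight from given mean/variance vectors
summariesFrom <- function(grid, means, vars, ns, ids = NULL) {
  k <- nrow(means)
  if (is.null(ids)) ids <- sprintf("c%02d", seq_len(k))
  lapply(seq_len(k), function(i)
    new("CohortSummary", cohortId = ids[i], meanMap = means[i, ],
        varianceMap = vars[i, ], nSubjects = as.integer(ns[i]),
        meanAge = 25, grid = grid))
}

# exchangeable noise cohorts with no planted signal
nullCohortSummaries <- function(grid, k = 6L, n = 12L, tau2 = 0.04,
                                seed = 1L) {
  truth <- makeGroundTruth(grid, nHubs = 0L, tau2 = tau2, seed = seed)
  summarizeCohorts(simulateCohortMaps(grid, truth, rep(n, k), seed = seed),
                   grid)
}

# a smooth Gaussian random field at given coordinates
smoothField <- function(coords, scaleMm = 15, seed = 1L) {
  set.seed(seed)
  W <- exp(-as.matrix(dist(coords))^2 / (2 * scaleMm^2))
  f <- as.numeric(W %*% rnorm(nrow(coords)))
  (f - mean(f)) / sd(f)
}

# lattice-spaced sample coordinates (expression samples sit > 1 voxel apart)
latticeCoords <- function(n = 500L, spacing = 12, span = 132, seed = 1L) {
  g <- expand.grid(x = seq(0, span, spacing), y = seq(0, span, spacing),
                   z = seq(0, span, spacing))
  set.seed(seed)
  as.matrix(g[sample(nrow(g), n), ])
}
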