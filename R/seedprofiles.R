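#' Seed specification
#'
#' A spherical seed region: all gray voxels whose centers lie within
#' \code{radiusMm} (inclusive) of \code{center}.
#'
#' @param center MNI mm coordinate triple.
#' @param radiusMm sphere radius in mm (default 6).
#' @return a list of class \code{SeedSpec}.
#' @export
SeedSpec <- function(center, radiusMm = 6) {
  stopifnot(length(center) == 3L, radiusMm > 0)
  structure(list(center = as.numeric(center), radiusMm = radiusMm),
            class = "SeedSpec")
}

# gray-voxel indices inside the seed sphere
.seedVoxels <- function(grid, seed) {
  d <- sqrt(colSums((t(coordsMm(grid)) - seed$center)^2))
  which(d <= seed$radiusMm)
}

#' Seed-to-whole-brain Fisher z connectivity map for one subject
#'
#' Averages the time series of all gray voxels in the seed sphere,
#' correlates the average with every voxel's series, and applies the
#' variance-stabilizing Fisher transform \code{z = arctanh(r)} with |r|
#' capped at 1 - 1e-7 (a voxel identical to the seed average would
#' otherwise map to infinity).
#'
#' @param timeseries time-by-voxel matrix for one subject.
#' @param seed a \code{\link{SeedSpec}}.
#' @param grid the session \linkS4class{VoxelGrid}.
#' @return a \linkS4class{VoxelMap} of Fisher z values.
#' @export
seedFisherZ <- function(timeseries, seed, grid) {
  vox <- .seedVoxels(grid, seed)
  if (!length(vox))
    stop("invalid seed: the sphere contains no gray voxels")
  s <- rowMeans(timeseries[, vox, drop = FALSE])
  if (!(stats::sd(s) > 0)) stop("seed series has zero variance")
  r <- as.numeric(stats::cor(s, timeseries))
  r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  VoxelMap(grid, atanh(r))
}

#' Seed-connectivity meta-analysis across cohorts
#'
#' The per-subject Fisher z maps of each cohort are summarized with the
#' same age/sex GLM as the FCS analysis, pooled with the random-effects
#' meta-analysis, and thresholded with the identical permutation
#' procedure, yielding the cohort-consistent connectivity map of the seed.
#'
#' @param zMapsByCohort list (one element per cohort) of subject-by-voxel
#'   matrices of Fisher z values.
#' @param ages,sexes lists of per-cohort covariate vectors.
#' @param grid the session \linkS4class{VoxelGrid}.
#' @param nPermutations,alpha,minClusterMm3,peakSeparationMm,seed passed
#'   to \code{\link{identifyHubs}}.
#' @return list with \code{meta}, \code{null} and \code{hubs} (the
#'   thresholded connectivity map) as in \code{\link{identifyHubs}}.
#' @export
seedMeta <- function(zMapsByCohort, ages, sexes, grid,
                     nPermutations = 1000L, alpha = 0.001,
                     minClusterMm3 = 200, peakSeparationMm = 15,
                     seed = 1L) {
  summaries <- lapply(seq_along(zMapsByCohort), function(c)
    fitCohortGlm(zMapsByCohort[[c]], ages[[c]], sexes[[c]],
                 sprintf("cohort%02d", c), grid)$summary)
  identifyHubs(summaries, nPermutations, alpha, minClusterMm3,
               peakSeparationMm, seed)
}

#' Network-coverage profile of a connectivity map
#'
#' To remove the effect of network size, coverage of network n is the
#' percentage of that network's gray voxels present in the significant
#' map: \code{100 * |map n network_n| / |network_n|}.
#'
#' @param significantMask logical vector or logical
#'   \linkS4class{VoxelMap} over gray voxels.
#' @param grid the session \linkS4class{VoxelGrid}.
#' @return numeric vector of percentages, one per network label (NaN with
#'   a warning for empty networks).
#' @export
connectivityProfile <- function(significantMask, grid) {
  if (is(significantMask, "VoxelMap"))
    significantMask <- as.logical(mapValues(significantMask))
  lab <- networkLabels(grid)
  nNet <- max(lab)
  out <- numeric(nNet)
  for (n in seq_len(nNet)) {
    tot <- sum(lab == n)
    if (tot == 0L) {
      warning("network ", n, " has no gray voxels; coverage is NaN")
      out[n] <- NaN
    } else out[n] <- 100 * sum(significantMask & lab == n) / tot
  }
  out
}

#' Hierarchical clustering of hub connectivity profiles
#'
#' Agglomerative clustering of the hub columns of a networks-by-hubs
#' coverage matrix using Euclidean distance and single linkage (the
#' documented defaults of the classic MATLAB \code{linkage} routine);
#' both are configurable.
#'
#' @param profiles numeric matrix, networks x hubs (H >= 2 columns).
#' @param k number of clusters to cut the tree into (optional).
#' @param method linkage method (default "single").
#' @return list with \code{tree} (an \code{hclust} object) and
#'   \code{assignment} (integer per hub; NULL when \code{k} is missing).
#' @export
clusterProfiles <- function(profiles, k = NULL, method = "single") {
  if (ncol(profiles) < 2L)
    stop("clustering needs at least two hub profiles")
  d <- stats::dist(t(profiles), method = "euclidean")
  tree <- stats::hclust(d, method = method)
  assignment <- if (is.null(k)) NULL else stats::cutree(tree, k = k)
  list(tree = tree, assignment = assignment)
}
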