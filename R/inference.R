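#' Max-statistic permutation null for the meta-analytic Z map
#'
#' Each iteration randomizes the spatial correspondence among the cohorts'
#' mean maps: an independent random voxel permutation is drawn per cohort
#' and applied jointly to that cohort's mean and variance maps (so the
#' mean/variance pairing within a cohort is preserved while cohorts are
#' spatially decoupled), the random-effects meta-analysis is recomputed,
#' and the map-wide maximum Z is recorded.
#'
#' @param summaries list of \linkS4class{CohortSummary} (k >= 2).
#' @param nIterations number of permutation iterations (>= 1).
#' @param seed integer RNG seed.
#' @return a \linkS4class{PermutationNull}.
#' @export
permutationNull <- function(summaries, nIterations = 10000L, seed = 1L) {
  k <- length(summaries)
  if (k < 2L) stop("insufficient cohorts: a meta-analysis needs k >= 2")
  if (nIterations < 1L) stop("'nIterations' must be >= 1")
  M <- do.call(rbind, lapply(summaries, function(s) s@meanMap))
  SD2 <- do.call(rbind, lapply(summaries, function(s) s@varianceMap))
  N <- vapply(summaries, function(s) as.numeric(s@nSubjects), numeric(1))
  nvox <- ncol(M)
  maxZ <- numeric(nIterations)
  Mp <- M; SD2p <- SD2
  withr_seed(seed, {
    for (it in seq_len(nIterations)) {
      for (i in seq_len(k)) {
        p <- sample.int(nvox)
        Mp[i, ] <- M[i, p]
        SD2p[i, ] <- SD2[i, p]
      }
      fit <- .dlMeta(Mp, SD2p, N, weights = FALSE)
      maxZ[it] <- max(fit$mStar / fit$se, na.rm = TRUE)
    }
  })
  new("PermutationNull", maxZ = maxZ, nIterations = as.integer(nIterations),
      seed = as.integer(seed))
}

#' Assign permutation p values to a Z map
#'
#' One-sided, add-one corrected:
#' \code{p(v) = (1 + #\{maxZ >= Z(v)\}) / (nIterations + 1)}, so p is never
#' zero and is monotone non-increasing in Z; tied Z values receive
#' identical p.
#'
#' @param zMap a \linkS4class{VoxelMap} of observed Z values.
#' @param null a \linkS4class{PermutationNull}.
#' @return a \linkS4class{VoxelMap} of p values.
#' @export
assignP <- function(zMap, null) {
  z <- mapValues(zMap)
  vs <- sort(null@maxZ)
  n <- length(vs)
  nGE <- n - findInterval(z, vs, left.open = TRUE)  # #{null >= z}
  p <- (1 + nGE) / (n + 1)
  p[is.na(z)] <- NA_real_
  VoxelMap(voxelGrid(zMap), p)
}

#' Threshold a p map into hub clusters
#'
#' Voxels with \code{p < alpha} are labeled into connected components
#' (26-neighborhood) and components with volume strictly greater than
#' \code{minClusterMm3} are retained.  Cluster labels are ordered by
#' decreasing voxel count (ties by smallest voxel index).
#'
#' @param pMap,zMap \linkS4class{VoxelMap}s of p and Z values.
#' @param alpha voxel threshold in (0, 1) (default 0.001).
#' @param minClusterMm3 minimum cluster volume in mm^3, exclusive
#'   (default 200).
#' @param grid the session \linkS4class{VoxelGrid}.
#' @param connectivity 26, 18 or 6 neighborhood.
#' @return a \linkS4class{HubResult} (peak table empty; see
#'   \code{\link{extractPeaks}}).
#' @export
thresholdHubs <- function(pMap, zMap, alpha = 0.001, minClusterMm3 = 200,
                          grid = voxelGrid(pMap), connectivity = 26L) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  if (minClusterMm3 < 0) stop("'minClusterMm3' must be >= 0")
  p <- mapValues(pMap)
  supra <- which(!is.na(p) & p < alpha)
  labels <- integer(length(p))
  if (length(supra)) {
    comp <- .connectedComponents(grid, supra, connectivity)
    sizes <- tabulate(comp)
    keepComp <- which(sizes * voxelVolume(grid) > minClusterMm3)
    if (length(keepComp)) {
      # stable relabeling: by decreasing size, ties by first voxel index
      firstVox <- vapply(keepComp, function(cc) min(supra[comp == cc]),
                         numeric(1))
      ord <- order(-sizes[keepComp], firstVox)
      newLab <- integer(max(comp))
      newLab[keepComp[ord]] <- seq_along(keepComp)
      lab <- newLab[comp]
      keepVox <- lab > 0L
      labels[supra[keepVox]] <- lab[keepVox]
    }
  }
  new("HubResult", pMap = p, hubMask = labels > 0L,
      clusterLabels = labels, peaks = .emptyPeaks(),
      alpha = alpha, minClusterMm3 = minClusterMm3, grid = grid)
}

.emptyPeaks <- function() {
  data.frame(cluster = integer(), x = numeric(), y = numeric(),
             z = numeric(), Z = numeric(), d = numeric(),
             mStar = numeric(), se = numeric())
}

# neighborhood offsets for a given connectivity
.neighborOffsets <- function(connectivity = 26L) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6L) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  if (connectivity == 18L) off <- off[rowSums(abs(off)) <= 2, , drop = FALSE]
  off
}

# connected components among the given gray-voxel indices
.connectedComponents <- function(grid, voxIdx, connectivity = 26L) {
  dims <- grid@dims
  n <- length(voxIdx)
  ijk <- arrayInd(grid@maskIdx[voxIdx], dims)
  look <- array(0L, dim = dims)
  look[grid@maskIdx[voxIdx]] <- seq_len(n)
  off <- .neighborOffsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (o in seq_len(nrow(off))) {
    nb <- sweep(ijk, 2L, off[o, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    lin <- nb[ok, 1] + dims[1] * ((nb[ok, 2] - 1) + dims[2] * (nb[ok, 3] - 1))
    hit <- look[lin]
    sel <- hit > 0L
    from <- c(from, which(ok)[sel])
    to <- c(to, hit[sel])
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  as.integer(igraph::components(g)$membership)
}

#' Extract hub peaks within each cluster
#'
#' Local maxima (Z strictly greater than every in-mask 26-neighborhood
#' neighbor) are sorted by Z descending (ties broken by lowest voxel
#' index) and greedily retained when at least \code{minSeparationMm} from
#' every already-retained peak of the same cluster.
#'
#' @param zMap a \linkS4class{VoxelMap} of Z values.
#' @param clusters a \linkS4class{HubResult} from
#'   \code{\link{thresholdHubs}}.
#' @param minSeparationMm minimum peak separation in mm (default 15).
#' @param meta optional \linkS4class{MetaResult} supplying the d, M* and
#'   SE columns of the peak table.
#' @return the \linkS4class{HubResult} with its peak table filled, rows
#'   sorted by Cohen's d (equivalently Z) descending.
#' @export
extractPeaks <- function(zMap, clusters, minSeparationMm = 15,
                         meta = NULL) {
  if (minSeparationMm < 0) stop("'minSeparationMm' must be >= 0")
  grid <- clusters@grid
  z <- mapValues(zMap)
  lab <- clusters@clusterLabels
  if (!any(lab > 0L)) {
    clusters@peaks <- .emptyPeaks()
    return(clusters)
  }
  dims <- grid@dims
  zArr <- array(-Inf, dim = dims)
  inMask <- array(FALSE, dim = dims)
  zArr[grid@maskIdx] <- z
  inMask[grid@maskIdx] <- TRUE
  off <- .neighborOffsets(26L)
  rows <- list()
  for (cl in sort(unique(lab[lab > 0L]))) {
    vox <- which(lab == cl)
    ijk <- arrayInd(grid@maskIdx[vox], dims)
    isMax <- rep(TRUE, length(vox))
    for (o in seq_len(nrow(off))) {
      nb <- sweep(ijk, 2L, off[o, ], "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
            nb[, 2] >= 1 & nb[, 2] <= dims[2] &
            nb[, 3] >= 1 & nb[, 3] <= dims[3]
      if (!any(ok)) next
      lin <- nb[ok, 1] + dims[1] * ((nb[ok, 2] - 1) + dims[2] * (nb[ok, 3] - 1))
      masked <- inMask[lin]
      ge <- zArr[lin] >= z[vox][ok]
      bad <- masked & ge
      isMax[which(ok)[bad]] <- FALSE
    }
    cand <- vox[isMax]
    if (!length(cand)) next
    cand <- cand[order(-z[cand], cand)]
    kept <- integer(0)
    for (v in cand) {
      if (!length(kept) ||
          all(sqrt(rowSums((grid@coordsMm[kept, , drop = FALSE] -
                            matrix(grid@coordsMm[v, ], length(kept), 3,
                                   byrow = TRUE))^2)) >= minSeparationMm))
        kept <- c(kept, v)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      cluster = cl,
      x = grid@coordsMm[kept, 1], y = grid@coordsMm[kept, 2],
      z = grid@coordsMm[kept, 3], Z = z[kept],
      d = if (is.null(meta)) NA_real_ else meta@d[kept],
      mStar = if (is.null(meta)) NA_real_ else meta@mStar[kept],
      se = if (is.null(meta)) NA_real_ else meta@se[kept],
      voxel = kept
    )
  }
  pk <- do.call(rbind, rows)
  if (is.null(pk)) {
    clusters@peaks <- .emptyPeaks()
    return(clusters)
  }
  pk <- pk[order(-pk$Z, pk$voxel), , drop = FALSE]
  pk$voxel <- NULL
  rownames(pk) <- NULL
  clusters@peaks <- pk
  clusters
}

#' Run the full hub-identification pipeline on cohort summaries
#'
#' Chains \code{\link{randomEffectsMeta}}, \code{\link{permutationNull}},
#' \code{\link{assignP}}, \code{\link{thresholdHubs}} and
#' \code{\link{extractPeaks}}.
#'
#' @param summaries list of \linkS4class{CohortSummary}.
#' @param nPermutations permutation iterations (default 10000).
#' @param alpha voxel threshold (default 0.001).
#' @param minClusterMm3 cluster-extent threshold in mm^3 (default 200).
#' @param peakSeparationMm peak separation in mm (default 15).
#' @param seed integer RNG seed for the permutations.
#' @return list with elements \code{meta} (\linkS4class{MetaResult}),
#'   \code{null} (\linkS4class{PermutationNull}) and \code{hubs}
#'   (\linkS4class{HubResult}).
#' @export
identifyHubs <- function(summaries, nPermutations = 10000L, alpha = 0.001,
                         minClusterMm3 = 200, peakSeparationMm = 15,
                         seed = 1L) {
  meta <- randomEffectsMeta(summaries)
  grid <- meta@grid
  null <- permutationNull(summaries, nPermutations, seed)
  zMap <- metaMap(meta, "z")
  pMap <- assignP(zMap, null)
  hubs <- thresholdHubs(pMap, zMap, alpha, minClusterMm3, grid)
  hubs <- extractPeaks(zMap, hubs, peakSeparationMm, meta)
  list(meta = meta, null = null, hubs = hubs)
}

#' @rdname accessors
#' @export
setMethod("hubMask", "HubResult", function(x) x@hubMask)

#' @rdname accessors
#' @export
setMethod("clusterLabels", "HubResult", function(x) x@clusterLabels)

#' @rdname accessors
#' @export
setMethod("hubPeaks", "HubResult", function(x) x@peaks)

#' @rdname accessors
#' @export
setMethod("pValues", "HubResult", function(x) x@pMap)

setMethod("show", "HubResult", function(object) {
  nc <- length(setdiff(unique(object@clusterLabels), 0L))
  cat(sprintf(
    "HubResult: %d hub voxels in %d cluster(s), %d peak(s); alpha = %g, extent > %g mm^3\n",
    sum(object@hubMask), nc, nrow(object@peaks), object@alpha,
    object@minClusterMm3))
})
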