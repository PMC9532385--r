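#' Dice's coefficient between two binary masks
#'
#' \code{2|A n B| / (|A| + |B|)}; defined as 1 when both masks are empty.
#'
#' @param a,b logical \linkS4class{VoxelMap}s or logical vectors on the
#'   same grid.
#' @return the overlap coefficient in [0, 1].
#' @export
dice <- function(a, b) {
  if (is(a, "VoxelMap") && is(b, "VoxelMap")) {
    .stopIfGridMismatch(voxelGrid(a), voxelGrid(b))
    a <- mapValues(a); b <- mapValues(b)
  }
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) stop("grid incompatibility: lengths differ")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Leave-one-cohort-out validation of the hub identification
#'
#' Reruns the full meta-analysis + permutation inference on each k-1
#' cohort subset and compares the result against the all-cohort reference:
#' Dice of the hub masks, and for each all-cohort peak the displacement to
#' the nearest reduced-set peak (nearest-peak matching, no one-to-one
#' constraint; Inf when the reduced run has no peaks).
#'
#' @param summaries list of \linkS4class{CohortSummary} (k >= 3).
#' @param nPermutations,alpha,minClusterMm3,peakSeparationMm,seed passed to
#'   \code{\link{identifyHubs}}.
#' @param reference optional precomputed all-cohort result from
#'   \code{\link{identifyHubs}} (recomputed if missing).
#' @return list with \code{locoDice} (named numeric per left-out cohort)
#'   and \code{peakDisplacements} (matrix, peaks x left-out cohorts, mm).
#' @export
leaveOneCohortOut <- function(summaries, nPermutations = 1000L,
                              alpha = 0.001, minClusterMm3 = 200,
                              peakSeparationMm = 15, seed = 1L,
                              reference = NULL) {
  k <- length(summaries)
  if (k < 3L) stop("insufficient cohorts: leave-one-out needs k >= 3")
  if (is.null(reference))
    reference <- identifyHubs(summaries, nPermutations, alpha,
                              minClusterMm3, peakSeparationMm, seed)
  refMask <- hubMask(reference$hubs)
  refPeaks <- hubPeaks(reference$hubs)
  ids <- vapply(summaries, cohortId, character(1))
  locoDice <- setNames(numeric(k), ids)
  disp <- matrix(NA_real_, nrow(refPeaks), k, dimnames = list(NULL, ids))
  for (i in seq_len(k)) {
    red <- identifyHubs(summaries[-i], nPermutations, alpha,
                        minClusterMm3, peakSeparationMm, seed)
    locoDice[i] <- dice(refMask, hubMask(red$hubs))
    rp <- hubPeaks(red$hubs)
    if (nrow(refPeaks)) {
      if (nrow(rp) == 0L) disp[, i] <- Inf
      else {
        for (pkr in seq_len(nrow(refPeaks))) {
          dd <- sqrt((rp$x - refPeaks$x[pkr])^2 +
                     (rp$y - refPeaks$y[pkr])^2 +
                     (rp$z - refPeaks$z[pkr])^2)
          disp[pkr, i] <- min(dd)
        }
      }
    }
  }
  list(locoDice = locoDice, peakDisplacements = disp)
}

#' Hub occurrence probability (HOP) across units
#'
#' Defines the \code{nTop} voxels with the highest map values of each unit
#' (subject or cohort) as that unit's hubs and reports, per voxel, the
#' fraction of units whose top set contains it.  Ties at the top-N
#' boundary are broken by voxel index (with a warning).
#'
#' @param maps numeric matrix, units x gray voxels.
#' @param nTop top-set size (1 <= nTop <= voxel count).
#' @return numeric HOP vector over gray voxels.
#' @export
hubOccurrence <- function(maps, nTop) {
  nvox <- ncol(maps)
  if (nTop < 1L || nTop > nvox)
    stop("'nTop' must lie in [1, voxel count]")
  counts <- numeric(nvox)
  tied <- FALSE
  for (u in seq_len(nrow(maps))) {
    v <- maps[u, ]
    ord <- order(-v, seq_len(nvox))
    if (nTop < nvox && v[ord[nTop]] == v[ord[nTop + 1L]]) tied <- TRUE
    counts[ord[seq_len(nTop)]] <- counts[ord[seq_len(nTop)]] + 1
  }
  if (tied)
    warning("ties at the top-N boundary were broken by voxel index")
  counts / nrow(maps)
}

#' Subsampling stability of the hub topography
#'
#' For each subset size, draws random unit subsets, recomputes the HOP
#' map, takes its top-N voxels (N = size of the reference mask) as the
#' subset's hub mask, and reports the mean and SD of Dice against the
#' reference across selections.
#'
#' @param maps numeric matrix, units x gray voxels.
#' @param referenceMask logical vector (or logical
#'   \linkS4class{VoxelMap} values) over gray voxels.
#' @param sizes integer vector of subset sizes (each <= unit count).
#' @param nSelections random selections per size (default 2000; a size
#'   equal to the full unit count has a single possible selection and is
#'   evaluated once).
#' @param seed integer RNG seed.
#' @return data.frame with columns size, meanDice, sdDice.
#' @export
subsampleStability <- function(maps, referenceMask, sizes,
                               nSelections = 2000L, seed = 1L) {
  if (is(referenceMask, "VoxelMap"))
    referenceMask <- as.logical(mapValues(referenceMask))
  nUnits <- nrow(maps)
  if (any(sizes > nUnits)) stop("subset size exceeds the unit count")
  nTop <- sum(referenceMask)
  if (nTop == 0L) stop("the reference mask is empty")
  withr_seed(seed, {
    out <- lapply(sizes, function(sz) {
      nSel <- if (sz == nUnits) 1L else nSelections
      dd <- vapply(seq_len(nSel), function(s) {
        sub <- maps[sample.int(nUnits, sz), , drop = FALSE]
        hop <- hubOccurrence(sub, nTop)
        top <- order(-hop, seq_along(hop))[seq_len(nTop)]
        mask <- logical(length(hop)); mask[top] <- TRUE
        dice(mask, referenceMask)
      }, numeric(1))
      data.frame(size = sz, meanDice = mean(dd),
                 sdDice = if (nSel > 1L) stats::sd(dd) else 0)
    })
    do.call(rbind, out)
  })
}
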