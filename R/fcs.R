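#' Connectivity-strength parameters
#'
#' Thresholds applied to the voxelwise correlation matrix before summing
#' connection weights: correlations below \code{rThreshold} are set to zero
#' (the boundary value \code{r == rThreshold} is kept), negative
#' correlations are excluded when \code{excludeNegative} is \code{TRUE},
#' and connections terminating within \code{minDistanceMm} (center-to-center
#' Euclidean distance \code{<= minDistanceMm}, a strict reading of
#' "within") are removed to avoid shared local signal.
#'
#' @param rThreshold correlation cutoff in [0, 1) (default 0.1).
#' @param minDistanceMm distance cutoff in mm (default 20).
#' @param excludeNegative drop negative correlations (default TRUE).
#' @return a list of class \code{FcsParams}.
#' @export
FcsParams <- function(rThreshold = 0.1, minDistanceMm = 20,
                      excludeNegative = TRUE) {
  if (rThreshold < 0 || rThreshold >= 1)
    stop("'rThreshold' must lie in [0, 1)")
  if (minDistanceMm < 0)
    stop("'minDistanceMm' must be >= 0")
  structure(list(rThreshold = rThreshold, minDistanceMm = minDistanceMm,
                 excludeNegative = excludeNegative), class = "FcsParams")
}

#' Compute raw functional connectivity strength (FCS)
#'
#' FCS of a voxel is the sum of suprathreshold connection weights between
#' that voxel and all other gray voxels:
#' \code{FCS(v) = sum_u r(v,u)} over pairs with \code{r >= rThreshold},
#' \code{r > 0} (when negatives are excluded) and center-to-center distance
#' \code{> minDistanceMm}.  The correlation matrix is evaluated in column
#' blocks so it is never fully materialized.
#'
#' @param x either a time-by-voxel matrix of rsfMRI time series for one
#'   subject, or a precomputed square voxel-by-voxel correlation matrix.
#' @param grid the session \linkS4class{VoxelGrid}.
#' @param params an \code{\link{FcsParams}} list.
#' @param blockSize number of voxels per evaluation block.
#' @return a \linkS4class{VoxelMap} of raw FCS values.  Zero-variance
#'   voxels are flagged with a warning and contribute no connections.
#' @export
computeFcs <- function(x, grid, params = FcsParams(), blockSize = 512L) {
  nvox <- nVoxels(grid)
  if (nvox < 2L) stop("FCS needs at least two gray voxels")
  isCorr <- is.matrix(x) && nrow(x) == ncol(x) && nrow(x) == nvox &&
    isTRUE(all.equal(unname(diag(x)), rep(1, nvox), tolerance = 1e-6))
  co <- coordsMm(grid)

  if (isCorr) {
    R <- x
    bad <- !is.finite(diag(R))
    if (any(bad)) {
      warning(sum(bad), " voxel(s) with non-finite correlations; ",
              "their connections were set to 0")
      R[bad, ] <- 0; R[, bad] <- 0
    }
    fcs <- numeric(nvox)
    for (start in seq(1L, nvox, by = blockSize)) {
      idx <- start:min(start + blockSize - 1L, nvox)
      blk <- R[, idx, drop = FALSE]
      fcs[idx] <- .fcsBlockSum(blk, co, idx, params)
    }
    return(VoxelMap(grid, fcs))
  }

  if (!is.matrix(x) || ncol(x) != nvox)
    stop("'x' must be a time-by-voxel matrix matching the grid, ",
         "or a square correlation matrix")
  sds <- apply(x, 2L, stats::sd)
  bad <- !(sds > 0) | !is.finite(sds)
  if (any(bad))
    warning(sum(bad), " zero-variance voxel(s); ",
            "their connections were set to 0")
  xs <- scale(x, center = TRUE, scale = FALSE)
  denom <- sds * sqrt(nrow(x) - 1)
  denom[bad] <- 1
  xs <- sweep(xs, 2L, denom, "/")
  xs[, bad] <- 0
  fcs <- numeric(nvox)
  for (start in seq(1L, nvox, by = blockSize)) {
    idx <- start:min(start + blockSize - 1L, nvox)
    blk <- crossprod(xs, xs[, idx, drop = FALSE])  # r(all, block)
    fcs[idx] <- .fcsBlockSum(blk, co, idx, params)
  }
  VoxelMap(grid, fcs)
}

# column sums of a thresholded correlation block (rows = all voxels)
.fcsBlockSum <- function(blk, co, idx, params) {
  n <- nrow(blk)
  d2 <- outer(rowSums(co^2), rep(1, length(idx))) -
    2 * co %*% t(co[idx, , drop = FALSE]) +
    outer(rep(1, n), rowSums(co[idx, , drop = FALSE]^2))
  keep <- blk >= params$rThreshold & d2 > params$minDistanceMm^2
  if (params$excludeNegative) keep <- keep & blk > 0
  keep[cbind(idx, seq_along(idx))] <- FALSE  # no self-connections
  colSums(blk * keep)
}

#' Normalize an FCS map to zero mean and unit SD across voxels
#'
#' Uses the population SD convention (divide by n), so a normalized map has
#' mean exactly 0 and population SD exactly 1 over the gray mask.
#'
#' @param raw a \linkS4class{VoxelMap} of raw FCS values.
#' @return a normalized \linkS4class{VoxelMap}.
#' @export
normalizeFcs <- function(raw) {
  v <- mapValues(raw)
  if (length(v) < 2L) stop("normalization needs >= 2 voxels")
  s <- sqrt(mean((v - mean(v))^2))
  if (!(s > 0)) stop("degenerate map: constant FCS cannot be normalized")
  VoxelMap(voxelGrid(raw), (v - mean(v)) / s)
}
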