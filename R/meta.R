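#' Voxelwise DerSimonian-Laird random-effects meta-analysis
#'
#' Pools per-cohort mean maps with inverse-variance weights, estimating the
#' between-cohort variance from the heterogeneity statistic.  Per voxel,
#' with cohort means M_i, residual variances SD_i^2 and sizes N_i:
#' \deqn{W_i = N_i / SD_i^2}
#' \deqn{Q = \sum W_i M_i^2 - (\sum W_i M_i)^2 / \sum W_i, \quad df = k-1}
#' \deqn{T^2 = \max(0, (Q - df) / (\sum W_i - \sum W_i^2/\sum W_i))}
#' \deqn{I^2 = \max(0, (Q - df)/Q) \times 100 \ (I^2 = 0\ when\ Q = 0)}
#' \deqn{W_i^* = 1 / (SD_i^2/N_i + T^2)}
#' \deqn{M^* = \sum W_i^* M_i / \sum W_i^*, \quad V = 1/\sum W_i^*, \quad
#'       SE = \sqrt{V}}
#' T^2 and I^2 are floored at zero when Q < df (the standard truncation).
#' Voxels where any cohort variance is non-positive are set to NaN with a
#' warning rather than poisoning the whole map.
#'
#' @param summaries list of \linkS4class{CohortSummary} (k >= 2).
#' @return a \linkS4class{MetaResult} with Z and Cohen's d filled in via
#'   \code{\link{effectSize}}.
#' @export
randomEffectsMeta <- function(summaries) {
  k <- length(summaries)
  if (k < 2L) stop("insufficient cohorts: a meta-analysis needs k >= 2")
  grid <- summaries[[1]]@grid
  for (s in summaries) .stopIfGridMismatch(grid, s@grid)
  M <- do.call(rbind, lapply(summaries, function(s) s@meanMap))
  SD2 <- do.call(rbind, lapply(summaries, function(s) s@varianceMap))
  N <- vapply(summaries, function(s) as.numeric(s@nSubjects), numeric(1))

  bad <- colSums(!(SD2 > 0) | !is.finite(SD2) | !is.finite(M)) > 0
  if (any(bad)) {
    warning(sum(bad), " voxel(s) with non-positive or non-finite cohort ",
            "variance were set to NaN")
    M[, bad] <- NaN
    SD2[, bad] <- 1  # placeholder; results at these voxels are NaN via M
  }

  fit <- .dlMeta(M, SD2, N)
  W <- N / SD2
  res <- new("MetaResult",
    mStar = fit$mStar, se = fit$se, variance = fit$variance, q = fit$q,
    df = k - 1L, tau2 = fit$tau2, i2 = fit$i2,
    z = rep(NA_real_, length(fit$mStar)),
    d = rep(NA_real_, length(fit$mStar)), k = as.integer(k),
    weightsOriginal = W, weightsUpdated = fit$wUpdated, grid = grid)
  effectSize(res)
}

# vectorized DL core over a cohorts-by-voxels matrix pair; no S4 overhead
# so the permutation loop can call it directly
.dlMeta <- function(M, SD2, N, weights = TRUE) {
  k <- nrow(M)
  W <- N / SD2
  SW <- colSums(W)
  SWM <- colSums(W * M)
  Q <- colSums(W * M^2) - SWM^2 / SW
  Q <- pmax(Q, 0)  # guard tiny negative rounding
  df <- k - 1
  C <- SW - colSums(W^2) / SW
  tau2 <- pmax(0, (Q - df) / C)
  i2 <- ifelse(Q > 0, pmax(0, (Q - df) / Q) * 100, 0)
  Ws <- 1 / (SD2 / N + rep(tau2, each = k))
  SWs <- colSums(Ws)
  mStar <- colSums(Ws * M) / SWs
  V <- 1 / SWs
  list(mStar = mStar, variance = V, se = sqrt(V), q = Q, tau2 = tau2,
       i2 = i2, wUpdated = if (weights) Ws else NULL)
}

#' Fill in the standardized effect and Cohen's d of a meta-analysis
#'
#' The pooled mean is compared against the global mean of the normalized
#' maps (zero): \code{Z = (M* - 0)/SE} and \code{d = Z/sqrt(k)} with k the
#' cohort count.
#'
#' @param result a \linkS4class{MetaResult}.
#' @return the result with slots \code{z} and \code{d} filled.
#' @export
effectSize <- function(result) {
  se <- result@se
  z <- result@mStar / se
  z[!(se > 0)] <- NaN
  if (any(!(se > 0), na.rm = TRUE))
    warning("voxels with SE = 0 were set to NaN")
  result@z <- z
  result@d <- z / sqrt(result@k)
  result
}

#' @rdname accessors
#' @export
setMethod("meanMap", "MetaResult", function(x) VoxelMap(x@grid, x@mStar))

setMethod("show", "MetaResult", function(object) {
  cat(sprintf(
    "MetaResult: k = %d cohorts, %d voxels; median I2 = %.1f%%, max d = %.3f\n",
    object@k, length(object@mStar),
    stats::median(object@i2, na.rm = TRUE),
    max(object@d, na.rm = TRUE)))
})

#' Extract per-voxel statistics of a MetaResult as VoxelMaps
#'
#' @param x a \linkS4class{MetaResult}.
#' @param what one of "mStar", "se", "variance", "q", "tau2", "i2", "z",
#'   "d".
#' @return a \linkS4class{VoxelMap}.
#' @export
metaMap <- function(x, what = c("mStar", "se", "variance", "q", "tau2",
                                "i2", "z", "d")) {
  what <- match.arg(what)
  VoxelMap(x@grid, slot(x, what))
}
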