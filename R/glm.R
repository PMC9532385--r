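#' Fit the per-cohort general linear model
#'
#' For every gray voxel, fits
#' \code{FCS = beta0 + betaAge*(Age - MeanAge) + betaSex*Sex + eps}
#' by least squares.  Age is centered at the cohort mean and sex is coded
#' +/-0.5 and centered at the cohort mean, so the intercept \code{beta0}
#' equals the covariate-adjusted cohort mean FCS.  The exported variance
#' map is the unbiased residual variance (divide by N - p, with p the
#' number of retained design columns); constant covariate columns (e.g. a
#' single-sex cohort) are dropped with a warning.
#'
#' @param subjectMaps numeric matrix (subjects x gray voxels) or list of
#'   \linkS4class{VoxelMap}.
#' @param ages numeric, years.
#' @param sexes 0/1 codes.
#' @param cohortId cohort identifier.
#' @param grid the session \linkS4class{VoxelGrid} (required when
#'   \code{subjectMaps} is a bare matrix).
#' @return a list with elements \code{summary}
#'   (\linkS4class{CohortSummary}) and \code{coefficients}
#'   (\linkS4class{GlmCoefficients}; slots are NA-filled when the
#'   corresponding column was dropped).
#' @export
fitCohortGlm <- function(subjectMaps, ages, sexes, cohortId = "cohort",
                         grid = NULL) {
  if (is.list(subjectMaps) && !is.matrix(subjectMaps)) {
    grid <- voxelGrid(subjectMaps[[1]])
    subjectMaps <- do.call(rbind, lapply(subjectMaps, mapValues))
  }
  if (is.null(grid)) stop("'grid' is required with a matrix input")
  n <- nrow(subjectMaps)
  if (n < 2L) stop("insufficient subjects: a cohort GLM needs >= 2")
  if (length(ages) != n || length(sexes) != n)
    stop("one age and one sex per subject are required")
  if (!all(is.finite(ages))) stop("ages must be finite")

  agec <- ages - mean(ages)
  sexc <- (as.numeric(sexes) - 0.5)
  sexc <- sexc - mean(sexc)

  cols <- list(intercept = rep(1, n))
  haveAge <- stats::var(agec) > 0
  haveSex <- stats::var(sexc) > 0
  if (haveAge) cols$age <- agec
  else warning("constant age in '", cohortId, "': age column dropped")
  if (haveSex) cols$sex <- sexc
  else warning("constant sex in '", cohortId, "': sex column dropped")
  X <- do.call(cbind, cols)
  p <- ncol(X)
  if (n <= p)
    stop("insufficient subjects: N must exceed the ", p,
         " design columns")

  qrX <- qr(X)
  if (qrX$rank < p) stop("design matrix is rank deficient")
  B <- qr.coef(qrX, subjectMaps)             # p x V
  res <- subjectMaps - X %*% B
  s2 <- colSums(res^2) / (n - p)

  beta0 <- B[1L, ]
  nv <- nVoxels(grid)
  betaAge <- if (haveAge) B[which(names(cols) == "age"), ] else
    rep(NA_real_, nv)
  betaSex <- if (haveSex) B[which(names(cols) == "sex"), ] else
    rep(NA_real_, nv)

  list(
    summary = new("CohortSummary", cohortId = as.character(cohortId),
                  meanMap = as.numeric(beta0), varianceMap = as.numeric(s2),
                  nSubjects = as.integer(n), meanAge = mean(ages),
                  grid = grid),
    coefficients = new("GlmCoefficients", beta0 = as.numeric(beta0),
                       betaAge = as.numeric(betaAge),
                       betaSex = as.numeric(betaSex))
  )
}

#' Fit GLMs for a list of synthetic cohorts
#'
#' Convenience wrapper applying \code{\link{fitCohortGlm}} to each
#' \linkS4class{SyntheticCohort}.
#'
#' @param cohorts list of \linkS4class{SyntheticCohort}.
#' @param grid the session \linkS4class{VoxelGrid}.
#' @return list of \linkS4class{CohortSummary}.
#' @export
summarizeCohorts <- function(cohorts, grid) {
  lapply(cohorts, function(ch)
    fitCohortGlm(ch@maps, ch@ages, ch@sexes, ch@cohortId, grid)$summary)
}

#' @rdname accessors
#' @export
setMethod("cohortId", "CohortSummary", function(x) x@cohortId)

#' @rdname accessors
#' @export
setMethod("nSubjects", "CohortSummary", function(x) x@nSubjects)

#' @rdname accessors
#' @export
setMethod("meanMap", "CohortSummary", function(x)
  VoxelMap(x@grid, x@meanMap))

#' @rdname accessors
#' @export
setMethod("varianceMap", "CohortSummary", function(x)
  VoxelMap(x@grid, x@varianceMap))

setMethod("show", "CohortSummary", function(object) {
  cat(sprintf("CohortSummary '%s': N = %d, mean age %.1f y, %d voxels\n",
              object@cohortId, object@nSubjects, object@meanAge,
              length(object@meanMap)))
})
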