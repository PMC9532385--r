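#' Define the generative ground truth for synthetic cohorts
#'
#' The generator mirrors the statistical structure assumed by the
#' downstream pipeline: a true mean normalized-FCS map on the z scale with
#' planted contiguous spherical hubs, Gaussian between-cohort heterogeneity
#' of variance \code{tau2}, within-cohort subject noise of SD
#' \code{sigmaWithin}, and linear age and sex effects.  Within each hub
#' sphere the amplitude ramps mildly (factor 1 at the rim to 1.2 at the
#' center) so every planted blob has a unique interior peak while all hub
#' voxels keep at least the nominal amplitude.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param nHubs number of planted spherical hubs (ignored when
#'   \code{hubCenters} is given).
#' @param hubRadiusMm hub sphere radius in mm.
#' @param hubAmplitude true mean at hub rim voxels (z-scale units).
#' @param hubCenters optional matrix (nHubs x 3) of hub centers in mm.
#' @param tau2 between-cohort variance (>= 0).
#' @param sigmaWithin within-cohort subject SD (> 0).
#' @param betaAge age slope per year.
#' @param betaSex sex contrast (code 1 minus code 0).
#' @param seed integer RNG seed.
#' @return a \linkS4class{GroundTruth}.
#' @export
makeGroundTruth <- function(grid, nHubs = 3L, hubRadiusMm = 7.5,
                            hubAmplitude = 0.5, hubCenters = NULL,
                            tau2 = 0.04, sigmaWithin = 1,
                            betaAge = -0.01, betaSex = 0.1, seed = 1L) {
  coords <- coordsMm(grid)
  nvox <- nVoxels(grid)
  if (is.null(hubCenters)) {
    hubCenters <- withr_seed(seed, {
      coords[sample.int(nvox, nHubs), , drop = FALSE]
    })
  }
  hubCenters <- rbind(hubCenters)
  mu <- numeric(nvox)
  inHub <- logical(nvox)
  for (h in seq_len(nrow(hubCenters))) {
    d <- sqrt(colSums((t(coords) - hubCenters[h, ])^2))
    inside <- d <= hubRadiusMm
    ramp <- hubAmplitude * (1 + 0.2 * (1 - d[inside] / hubRadiusMm))
    mu[inside] <- pmax(mu[inside], ramp)
    inHub <- inHub | inside
  }
  new("GroundTruth", trueMeanMap = mu, tau2 = tau2,
      sigmaWithin = sigmaWithin, betaAge = betaAge, betaSex = betaSex,
      hubMaskTrue = inHub, seed = as.integer(seed))
}

#' Simulate multi-cohort subject-level normalized FCS maps
#'
#' Each subject map is
#' \code{trueMeanMap + u_c + betaAge*(age - meanAge_c) + betaSex*sex + eps},
#' with a cohort effect \code{u_c(v) ~ N(0, tau2)} drawn independently per
#' cohort (and, by default, per voxel) and subject noise
#' \code{eps ~ N(0, sigmaWithin^2)}.  Ages are uniform on [18, 36] years
#' and sexes Bernoulli(0.5), mirroring a healthy-young-adult inclusion
#' window.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param truth a \linkS4class{GroundTruth}.
#' @param cohortSizes integer vector of subject counts (all >= 2).
#' @param seed integer RNG seed.
#' @param smoothCohortEffect if \code{TRUE}, the cohort effect is spatially
#'   smoothed (Gaussian kernel, 2-voxel scale) and rescaled back to
#'   variance \code{tau2}, for more realistic spatial structure.
#' @return list of \linkS4class{SyntheticCohort}.
#' @export
simulateCohortMaps <- function(grid, truth, cohortSizes, seed = 1L,
                               smoothCohortEffect = FALSE) {
  cohortSizes <- as.integer(cohortSizes)
  if (any(cohortSizes < 2L))
    stop("every cohort size must be >= 2")
  nvox <- nVoxels(grid)
  withr_seed(seed, {
    lapply(seq_along(cohortSizes), function(c) {
      n <- cohortSizes[c]
      u <- rnorm(nvox, 0, sqrt(truth@tau2))
      if (smoothCohortEffect && truth@tau2 > 0) {
        u <- .smoothFieldGrid(grid, u, 2 * grid@voxelSizeMm)
        u <- u / stats::sd(u) * sqrt(truth@tau2)
      }
      ages <- runif(n, 18, 36)
      sexes <- rbinom(n, 1L, 0.5)
      base <- truth@trueMeanMap + u
      maps <- matrix(rnorm(n * nvox, 0, truth@sigmaWithin), n, nvox)
      maps <- maps + rep(base, each = n) +
        truth@betaAge * (ages - mean(ages)) + truth@betaSex * sexes
      new("SyntheticCohort", cohortId = sprintf("cohort%02d", c),
          maps = maps, ages = ages, sexes = as.integer(sexes))
    })
  })
}

# Gaussian-kernel smoothing of a per-gray-voxel field (small grids only)
.smoothFieldGrid <- function(grid, values, scaleMm) {
  co <- coordsMm(grid)
  W <- exp(-as.matrix(stats::dist(co))^2 / (2 * scaleMm^2))
  as.numeric((W %*% values) / rowSums(W))
}

#' Simulate a cohort of voxel time series with planted community structure
#'
#' Draws stationary multivariate Gaussian series whose population
#' correlation matrix follows \code{communitySpec}: either a full
#' correlation matrix, or a list with elements \code{blocks} (list of
#' gray-voxel index vectors) and \code{r} (within-block correlation,
#' recycled across blocks) on an identity background.  Voxels inside a
#' correlated block acquire high degree and therefore high FCS.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param communitySpec correlation matrix or block description (see
#'   above).
#' @param nTimepoints number of time points (>= 30).
#' @param seed integer RNG seed.
#' @param nSubjects number of independent subjects to draw (default 1).
#' @return list of \code{nSubjects} matrices, time x gray voxels.
#' @export
simulateTimeseriesCohort <- function(grid, communitySpec, nTimepoints,
                                     seed = 1L, nSubjects = 1L) {
  if (nTimepoints < 30L)
    stop("'nTimepoints' must be >= 30")
  nvox <- nVoxels(grid)
  R <- if (is.matrix(communitySpec)) communitySpec else {
    stopifnot(is.list(communitySpec), !is.null(communitySpec$blocks))
    r <- rep(communitySpec$r, length.out = length(communitySpec$blocks))
    M <- diag(nvox)
    for (b in seq_along(communitySpec$blocks)) {
      idx <- communitySpec$blocks[[b]]
      M[idx, idx] <- r[b]
      diag(M)[idx] <- 1
    }
    M
  }
  if (!isTRUE(all.equal(dim(R), c(nvox, nvox), check.attributes = FALSE)))
    stop("correlation matrix must be gray-voxel square")
  ch <- tryCatch(chol(R),
                 error = function(e) stop("community correlation matrix is ",
                                          "not positive definite"))
  withr_seed(seed, {
    lapply(seq_len(nSubjects), function(s) {
      matrix(rnorm(nTimepoints * nvox), nTimepoints, nvox) %*% ch
    })
  })
}

#' Simulate an expression matrix with label-informative genes
#'
#' Samples are placed at gray-mask voxel centers; the first \code{nHub}
#' samples are labeled \code{hub}, the rest \code{nonhub}.  Informative
#' genes mimic a co-expressed gene set: each is
#' \code{sqrt(w) * L + sqrt(1 - w) * noise + effect * 1[hub]}, where
#' \code{L} is one shared spatially smoothed unit-variance Gaussian
#' field over the sample coordinates (kernel scale
#' \code{spatialScaleMm}) and \code{w = sharedVariance}.  Every
#' informative gene therefore has population standardized hub/non-hub
#' mean difference \code{effect}, genes within the set are correlated
#' (as co-regulated genes are), and the set's pooled classification
#' signal saturates at \code{effect/sqrt(w)} instead of growing without
#' bound in the gene count.  Uninformative genes are label-independent
#' i.i.d. standard normals.
#'
#' @param nHub,nNonhub sample counts per class (> 0).
#' @param nGenes total genes.
#' @param nInformative number of label-informative genes
#'   (<= \code{nGenes}).
#' @param effect standardized hub-minus-nonhub mean shift.
#' @param spatialScaleMm smoothing scale of the shared field in mm.
#' @param grid a \linkS4class{VoxelGrid}.
#' @param seed integer RNG seed.
#' @param sharedVariance variance share of the shared smooth field in
#'   each informative gene (in [0, 1), default 0.2; together with the
#'   label-driven component this realizes pairwise co-expression
#'   correlations near 0.35 at \code{effect = 1}, typical of a
#'   co-regulated module).
#' @return a \linkS4class{HubExpression}; \code{rowData()$informative}
#'   flags the truly informative genes.
#' @export
simulateExpression <- function(nHub, nNonhub, nGenes, nInformative,
                               effect = 1, spatialScaleMm = 15,
                               grid, seed = 1L, sharedVariance = 0.2) {
  if (nHub <= 0L || nNonhub <= 0L || nGenes <= 0L)
    stop("sample and gene counts must be positive")
  if (nInformative > nGenes)
    stop("'nInformative' cannot exceed 'nGenes'")
  if (sharedVariance < 0 || sharedVariance >= 1)
    stop("'sharedVariance' must lie in [0, 1)")
  n <- nHub + nNonhub
  nvox <- nVoxels(grid)
  withr_seed(seed, {
    pos <- sample.int(nvox, n, replace = n > nvox)
    co <- coordsMm(grid)[pos, , drop = FALSE]
    labels <- c(rep("hub", nHub), rep("nonhub", nNonhub))
    X <- matrix(rnorm(n * nGenes), n, nGenes)
    if (nInformative > 0L) {
      W <- exp(-as.matrix(stats::dist(co))^2 / (2 * spatialScaleMm^2))
      L <- as.numeric(W %*% rnorm(n))
      L <- (L - mean(L)) / stats::sd(L)
      idx <- seq_len(nInformative)
      X[, idx] <- sqrt(sharedVariance) * L +
        sqrt(1 - sharedVariance) * X[, idx, drop = FALSE] +
        effect * (labels == "hub")
    }
    colnames(X) <- sprintf("gene%05d", seq_len(nGenes))
    rownames(X) <- sprintf("sample%05d", seq_len(n))
    HubExpression(X, co, labels,
                  informative = seq_len(nGenes) <= nInformative)
  })
}

#' Construct a HubExpression container
#'
#' @param values numeric matrix, samples x genes, with dimnames.
#' @param coords numeric matrix, samples x 3 (mm).
#' @param labels character/factor with levels hub, nonhub, excluded.
#' @param informative optional logical per gene, stored in
#'   \code{rowData()}.
#' @return a \linkS4class{HubExpression}.
#' @export
HubExpression <- function(values, coords, labels, informative = NULL) {
  coords <- rbind(coords)
  cd <- S4Vectors::DataFrame(
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    label = factor(as.character(labels),
                   levels = c("hub", "nonhub", "excluded")),
    row.names = rownames(values)
  )
  rd <- if (is.null(informative)) NULL else
    S4Vectors::DataFrame(informative = informative,
                         row.names = colnames(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = t(values)), colData = cd, rowData = rd
  )
  new("HubExpression", se)
}

#' @rdname accessors
#' @export
setMethod("exprValues", "HubExpression", function(x)
  t(SummarizedExperiment::assay(x, "expr")))

#' @rdname accessors
#' @export
setMethod("sampleCoords", "HubExpression", function(x) {
  cd <- SummarizedExperiment::colData(x)
  cbind(x = cd$x, y = cd$y, z = cd$z)
})

#' @rdname accessors
#' @export
setMethod("sampleLabels", "HubExpression", function(x)
  as.character(SummarizedExperiment::colData(x)$label))

#' Write simulated cohorts to disk
#'
#' One NIfTI volume per subject plus a tab-separated covariate sheet
#' (columns subject, age, sex) per cohort.
#'
#' @param cohorts list of \linkS4class{SyntheticCohort}.
#' @param grid the session \linkS4class{VoxelGrid}.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
writeCohorts <- function(cohorts, grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in cohorts) {
    cdir <- file.path(dir, ch@cohortId)
    dir.create(cdir, showWarnings = FALSE)
    for (s in seq_len(nrow(ch@maps))) {
      writeVolume(VoxelMap(grid, ch@maps[s, ]),
                  file.path(cdir, sprintf("subject%03d.nii.gz", s)))
    }
    utils::write.table(
      data.frame(subject = sprintf("subject%03d", seq_len(nrow(ch@maps))),
                 age = ch@ages, sex = ch@sexes),
      file.path(cdir, "covariates.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
  }
  invisible(dir)
}
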