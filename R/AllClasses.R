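#' @import methods
#' @importFrom stats cor sd var rnorm runif rbinom quantile median mad
#'   hclust cutree lowess approx prcomp setNames wilcox.test
NULL

#' VoxelGrid: the spatial frame shared by every map in a session
#'
#' A \code{VoxelGrid} holds the voxel lattice (dimensions, isotropic voxel
#' size, affine voxel-index-to-mm transform), the gray-matter mask, and the
#' per-voxel network labels (seven cortical networks plus one subcortical
#' network in the canonical parcellation, but any number of labels is
#' allowed).  All maps are stored as flat vectors over the gray-mask voxels
#' in a fixed (column-major) voxel ordering, recorded once in
#' \code{maskIdx}; \code{coordsMm} caches the mm coordinates of those
#' voxels.
#'
#' @slot dims integer(3), array dimensions.
#' @slot voxelSizeMm numeric(1), isotropic voxel edge length in mm.
#' @slot affine 4x4 matrix mapping 0-based voxel indices to mm coordinates.
#' @slot grayMask logical array of dimension \code{dims}.
#' @slot networkLabels integer array of dimension \code{dims}; 0 outside the
#'   gray mask, 1..nNetworks inside.
#' @slot maskIdx integer vector of column-major linear indices of gray
#'   voxels (the canonical voxel ordering).
#' @slot coordsMm numeric matrix (nVoxels x 3) of gray-voxel centers in mm.
#' @exportClass VoxelGrid
setClass("VoxelGrid",
  representation(
    dims = "integer",
    voxelSizeMm = "numeric",
    affine = "matrix",
    grayMask = "array",
    networkLabels = "array",
    maskIdx = "integer",
    coordsMm = "matrix"
  )
)

setValidity("VoxelGrid", function(object) {
  msg <- character()
  if (length(object@dims) != 3L || any(object@dims <= 0L))
    msg <- c(msg, "'dims' must be three positive integers")
  if (object@voxelSizeMm <= 0)
    msg <- c(msg, "'voxelSizeMm' must be positive")
  if (!all(dim(object@affine) == c(4L, 4L)) ||
      abs(det(object@affine)) < .Machine$double.eps)
    msg <- c(msg, "'affine' must be an invertible 4x4 matrix")
  if (!identical(dim(object@grayMask), object@dims))
    msg <- c(msg, "'grayMask' dimensions disagree with 'dims'")
  if (!identical(dim(object@networkLabels), object@dims))
    msg <- c(msg, "'networkLabels' dimensions disagree with 'dims'")
  if (any(object@networkLabels[!object@grayMask] != 0L))
    msg <- c(msg, "network labels must be zero outside the gray mask")
  if (length(object@maskIdx) != sum(object@grayMask))
    msg <- c(msg, "'maskIdx' length disagrees with the gray mask")
  if (nrow(object@coordsMm) != length(object@maskIdx))
    msg <- c(msg, "'coordsMm' rows disagree with 'maskIdx'")
  if (length(msg)) msg else TRUE
})

#' VoxelMap: one scalar per gray-mask voxel
#'
#' Carrier for FCS, Z, p, Cohen's d, I2 and similar per-voxel quantities.
#' Values are kept as a flat vector over the gray-mask voxels in the
#' grid's canonical ordering.
#'
#' @slot grid the session \code{VoxelGrid}.
#' @slot values numeric vector, one value per gray-mask voxel.
#' @exportClass VoxelMap
setClass("VoxelMap",
  representation(grid = "VoxelGrid", values = "numeric")
)

setValidity("VoxelMap", function(object) {
  if (length(object@values) != length(object@grid@maskIdx))
    "'values' length must equal the gray-mask voxel count"
  else TRUE
})

#' GroundTruth: generative parameters for the synthetic cohorts
#'
#' @slot trueMeanMap numeric, true normalized FCS per gray voxel (z scale).
#' @slot tau2 numeric(1), between-cohort variance (>= 0).
#' @slot sigmaWithin numeric(1), within-cohort subject SD (> 0).
#' @slot betaAge numeric(1), age slope per year.
#' @slot betaSex numeric(1), sex contrast.
#' @slot hubMaskTrue logical, planted-hub indicator per gray voxel.
#' @slot seed integer(1) RNG seed used to build the truth.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    trueMeanMap = "numeric", tau2 = "numeric", sigmaWithin = "numeric",
    betaAge = "numeric", betaSex = "numeric", hubMaskTrue = "logical",
    seed = "integer"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (object@tau2 < 0) msg <- c(msg, "'tau2' must be >= 0")
  if (object@sigmaWithin <= 0) msg <- c(msg, "'sigmaWithin' must be > 0")
  if (length(object@hubMaskTrue) != length(object@trueMeanMap))
    msg <- c(msg, "hub mask and mean map lengths differ")
  if (length(msg)) msg else TRUE
})

#' SyntheticCohort: simulated per-subject normalized FCS maps
#'
#' @slot cohortId character(1).
#' @slot maps numeric matrix, subjects x gray voxels.
#' @slot ages numeric, years.
#' @slot sexes integer, 0/1 codes.
#' @exportClass SyntheticCohort
setClass("SyntheticCohort",
  representation(cohortId = "character", maps = "matrix",
                 ages = "numeric", sexes = "integer")
)

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  if (nrow(object@maps) < 2L) msg <- c(msg, "a cohort needs >= 2 subjects")
  if (length(object@ages) != nrow(object@maps) ||
      length(object@sexes) != nrow(object@maps))
    msg <- c(msg, "one age and sex per subject map is required")
  if (length(msg)) msg else TRUE
})

#' CohortSummary: the per-cohort input to the meta-analysis
#'
#' Mean map (the GLM intercept, i.e. the covariate-adjusted cohort mean),
#' residual-variance map, subject count and mean age of one cohort.
#'
#' @slot cohortId character(1).
#' @slot meanMap numeric, adjusted cohort mean per gray voxel (M_i).
#' @slot varianceMap numeric, unbiased residual variance per voxel (SD_i^2).
#' @slot nSubjects integer(1), N_i.
#' @slot meanAge numeric(1), cohort mean age in years.
#' @slot grid the session \code{VoxelGrid}.
#' @exportClass CohortSummary
setClass("CohortSummary",
  representation(cohortId = "character", meanMap = "numeric",
                 varianceMap = "numeric", nSubjects = "integer",
                 meanAge = "numeric", grid = "VoxelGrid")
)

setValidity("CohortSummary", function(object) {
  msg <- character()
  if (object@nSubjects < 2L) msg <- c(msg, "'nSubjects' must be >= 2")
  if (any(object@varianceMap < 0, na.rm = TRUE))
    msg <- c(msg, "variance map must be non-negative")
  if (length(object@meanMap) != length(object@grid@maskIdx) ||
      length(object@varianceMap) != length(object@grid@maskIdx))
    msg <- c(msg, "maps must cover the gray mask")
  if (length(msg)) msg else TRUE
})

#' GlmCoefficients: fitted cohort GLM slopes
#'
#' @slot beta0 numeric, intercept map (adjusted cohort mean).
#' @slot betaAge numeric, age slope per year (NA if the column was dropped).
#' @slot betaSex numeric, sex contrast (NA if the column was dropped).
#' @exportClass GlmCoefficients
setClass("GlmCoefficients",
  representation(beta0 = "numeric", betaAge = "numeric", betaSex = "numeric")
)

#' MetaResult: voxelwise DerSimonian-Laird random-effects meta-analysis
#'
#' Per-voxel pooled mean M*, its standard error and variance, the
#' heterogeneity statistic Q with df = k - 1, the between-cohort variance
#' estimate T^2, the heterogeneity percentage I^2, the standardized effect
#' Z = M*/SE and Cohen's d = Z/sqrt(k), plus the original (N_i/SD_i^2) and
#' updated (1/(SD_i^2/N_i + T^2)) cohort weights as diagnostics.
#'
#' @slot mStar,se,variance,q,tau2,i2,z,d numeric per-voxel vectors.
#' @slot df integer(1), k - 1.
#' @slot k integer(1), number of cohorts.
#' @slot weightsOriginal,weightsUpdated numeric matrices, cohorts x voxels.
#' @slot grid the session \code{VoxelGrid}.
#' @exportClass MetaResult
setClass("MetaResult",
  representation(
    mStar = "numeric", se = "numeric", variance = "numeric",
    q = "numeric", df = "integer", tau2 = "numeric", i2 = "numeric",
    z = "numeric", d = "numeric", k = "integer",
    weightsOriginal = "matrix", weightsUpdated = "matrix",
    grid = "VoxelGrid"
  )
)

setValidity("MetaResult", function(object) {
  msg <- character()
  if (object@k < 2L) msg <- c(msg, "a meta-analysis needs k >= 2 cohorts")
  if (any(object@tau2 < 0, na.rm = TRUE)) msg <- c(msg, "tau2 must be >= 0")
  if (any(object@i2 < 0 | object@i2 >= 100, na.rm = TRUE))
    msg <- c(msg, "I2 must lie in [0, 100)")
  if (length(msg)) msg else TRUE
})

#' PermutationNull: max-statistic null distribution
#'
#' @slot maxZ numeric, one map-wide maximum Z per permutation iteration.
#' @slot nIterations integer(1).
#' @slot seed integer(1).
#' @exportClass PermutationNull
setClass("PermutationNull",
  representation(maxZ = "numeric", nIterations = "integer", seed = "integer")
)

setValidity("PermutationNull", function(object) {
  if (length(object@maxZ) != object@nIterations)
    "'maxZ' length must equal 'nIterations'"
  else TRUE
})

#' HubResult: thresholded hub mask, labeled clusters, and peak table
#'
#' @slot pMap numeric, permutation p value per gray voxel.
#' @slot hubMask logical, voxels surviving p < alpha and the cluster-extent
#'   rule.
#' @slot clusterLabels integer, 0 outside hubs, 1..m inside (labels ordered
#'   by decreasing cluster size).
#' @slot peaks data.frame with columns cluster, x, y, z (mm), Z, d, mStar,
#'   se, sorted by d descending.
#' @slot alpha,minClusterMm3 numeric(1), thresholds used.
#' @slot grid the session \code{VoxelGrid}.
#' @exportClass HubResult
setClass("HubResult",
  representation(
    pMap = "numeric", hubMask = "logical", clusterLabels = "integer",
    peaks = "data.frame", alpha = "numeric", minClusterMm3 = "numeric",
    grid = "VoxelGrid"
  )
)

setValidity("HubResult", function(object) {
  msg <- character()
  if (any(object@hubMask & !(object@pMap < object@alpha)))
    msg <- c(msg, "hub voxels must satisfy p < alpha")
  if (any(object@hubMask & object@clusterLabels == 0L))
    msg <- c(msg, "every hub voxel must carry a cluster label")
  if (length(msg)) msg else TRUE
})

#' SurrogateSet: autocorrelation-preserving surrogate maps
#'
#' Each surrogate carries exactly the source's value multiset (enforced by
#' final rank re-assignment) arranged so that its binned variogram tracks
#' the source's.
#'
#' @slot source numeric, source values per location.
#' @slot surrogates numeric matrix, n x locations.
#' @slot coords numeric matrix, locations x 3 (mm).
#' @slot n integer(1), number of surrogates.
#' @slot seed integer(1).
#' @slot params list of generator settings (knn, nBins, bandwidths).
#' @exportClass SurrogateSet
setClass("SurrogateSet",
  representation(source = "numeric", surrogates = "matrix",
                 coords = "matrix", n = "integer", seed = "integer",
                 params = "list")
)

setValidity("SurrogateSet", function(object) {
  msg <- character()
  if (nrow(object@surrogates) != object@n)
    msg <- c(msg, "'surrogates' must have n rows")
  if (ncol(object@surrogates) != length(object@source))
    msg <- c(msg, "surrogate length must match the source")
  if (length(msg)) msg else TRUE
})

#' HubExpression: expression samples with coordinates and hub labels
#'
#' A \code{SummarizedExperiment} (genes as rows, samples as columns) whose
#' \code{colData} records the sample MNI coordinates (\code{x}, \code{y},
#' \code{z}, mm) and the \code{label} factor with levels \code{hub},
#' \code{nonhub}, \code{excluded}.
#'
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass HubExpression
setClass("HubExpression", contains = "SummarizedExperiment")

setValidity("HubExpression", function(object) {
  cd <- SummarizedExperiment::colData(object)
  msg <- character()
  if (!all(c("x", "y", "z", "label") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'x', 'y', 'z', 'label'")
  else {
    if (!all(is.finite(cd$x) & is.finite(cd$y) & is.finite(cd$z)))
      msg <- c(msg, "sample coordinates must be finite")
    if (!all(as.character(cd$label) %in% c("hub", "nonhub", "excluded")))
      msg <- c(msg, "labels must be 'hub', 'nonhub' or 'excluded'")
  }
  if (any(is.na(SummarizedExperiment::assay(object))))
    msg <- c(msg, "expression values must not be missing")
  if (length(msg)) msg else TRUE
})
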