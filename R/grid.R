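#' Build a synthetic voxel grid with gray mask and network labels
#'
#' Constructs an isotropic voxel lattice centered on the origin, marks every
#' voxel as gray matter, and partitions the mask into \code{nNetworks}
#' contiguous labels via a seeded Voronoi tessellation of randomly chosen
#' voxel centers.  The affine maps 0-based voxel indices to mm so that the
#' grid center sits at (0, 0, 0), mimicking an MNI-like frame.
#'
#' @param dims integer(3), array dimensions (all positive).
#' @param voxelSizeMm isotropic voxel edge length in mm (default 3).
#' @param nNetworks number of network labels (>= 2, default 8: seven
#'   cortical networks plus one subcortical).
#' @param seed integer RNG seed for the label tessellation.
#' @return a \linkS4class{VoxelGrid}.
#' @examples
#' g <- makeGrid(c(10, 10, 10))
#' nVoxels(g)   # 1000
#' @export
makeGrid <- function(dims, voxelSizeMm = 3, nNetworks = 8L, seed = 1L) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims <= 0L) || anyNA(dims))
    stop("'dims' must be three positive integers")
  if (nNetworks < 2L)
    stop("'nNetworks' must be >= 2")
  nvox <- prod(dims)
  if (nNetworks > nvox)
    stop("more networks than voxels")

  origin <- -(dims - 1) / 2 * voxelSizeMm
  affine <- diag(c(rep(voxelSizeMm, 3), 1))
  affine[1:3, 4] <- origin

  gray <- array(TRUE, dim = dims)
  maskIdx <- which(gray)
  ijk <- arrayInd(maskIdx, dims) - 1L
  coords <- sweep(ijk * voxelSizeMm, 2L, -origin, "-")
  colnames(coords) <- c("x", "y", "z")

  labels <- withr_seed(seed, {
    centers <- sample.int(nvox, nNetworks)
    cc <- coords[centers, , drop = FALSE]
    # nearest Voronoi center, ties to the lowest label for determinism
    d2 <- outer(rowSums(coords^2), rep(1, nNetworks)) -
      2 * coords %*% t(cc) + outer(rep(1, nvox), rowSums(cc^2))
    max.col(-d2, ties.method = "first")
  })
  lab <- array(0L, dim = dims)
  lab[maskIdx] <- as.integer(labels)

  new("VoxelGrid", dims = dims, voxelSizeMm = voxelSizeMm, affine = affine,
      grayMask = gray, networkLabels = lab, maskIdx = maskIdx,
      coordsMm = coords)
}

# run expr under a local RNG seed without disturbing the caller's stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Construct a VoxelMap
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param values numeric vector over the gray-mask voxels (recycled if
#'   length 1).
#' @return a \linkS4class{VoxelMap}.
#' @export
VoxelMap <- function(grid, values) {
  if (length(values) == 1L) values <- rep(values, length(grid@maskIdx))
  new("VoxelMap", grid = grid, values = as.numeric(values))
}

#' @rdname accessors
#' @export
setMethod("nVoxels", "VoxelGrid", function(x) length(x@maskIdx))

#' @rdname accessors
#' @export
setMethod("voxelVolume", "VoxelGrid", function(x) x@voxelSizeMm^3)

#' @rdname accessors
#' @export
setMethod("coordsMm", "VoxelGrid", function(x) x@coordsMm)

#' @rdname accessors
#' @export
setMethod("grayMask", "VoxelGrid", function(x) x@grayMask)

#' @param asArray return the full 3-D label array instead of the
#'   per-gray-voxel vector.
#' @rdname accessors
#' @export
setMethod("networkLabels", "VoxelGrid", function(x, asArray = FALSE) {
  if (asArray) x@networkLabels else as.integer(x@networkLabels[x@maskIdx])
})

#' @rdname accessors
#' @export
setMethod("voxelGrid", "VoxelMap", function(x) x@grid)

#' @rdname accessors
#' @export
setMethod("mapValues", "VoxelMap", function(x) x@values)

setMethod("show", "VoxelGrid", function(object) {
  cat("VoxelGrid:", paste(object@dims, collapse = " x "),
      sprintf("voxels at %.3g mm;", object@voxelSizeMm),
      nVoxels(object), "gray voxels;",
      length(unique(networkLabels(object))), "networks\n")
})

setMethod("show", "VoxelMap", function(object) {
  v <- object@values
  cat(sprintf("VoxelMap over %d gray voxels: range [%.4g, %.4g], mean %.4g\n",
              length(v), min(v, na.rm = TRUE), max(v, na.rm = TRUE),
              mean(v, na.rm = TRUE)))
})

#' Euclidean center-to-center distance between two gray voxels
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param i,j 1-based indices into the gray-mask voxel ordering.
#' @return distance in mm.
#' @export
euclideanDistanceMm <- function(grid, i, j) {
  n <- nVoxels(grid)
  if (any(c(i, j) < 1L) || any(c(i, j) > n))
    stop("voxel index outside the gray mask")
  sqrt(sum((grid@coordsMm[i, ] - grid@coordsMm[j, ])^2))
}

# both grids describe the same lattice?
.sameGrid <- function(a, b, tol = 1e-6) {
  identical(a@dims, b@dims) &&
    abs(a@voxelSizeMm - b@voxelSizeMm) < tol &&
    max(abs(a@affine - b@affine)) < tol &&
    identical(a@maskIdx, b@maskIdx)
}

.stopIfGridMismatch <- function(a, b) {
  if (!.sameGrid(a, b)) stop("grid incompatibility: maps live on different grids")
  invisible(TRUE)
}

# mm coordinates -> 1-based gray-voxel index (NA when outside mask/array)
.mmToMaskIndex <- function(grid, xyz) {
  xyz <- rbind(xyz)
  inv <- solve(grid@affine)
  h <- cbind(xyz, 1) %*% t(inv)
  ijk <- round(h[, 1:3, drop = FALSE])
  ok <- ijk[, 1] >= 0 & ijk[, 1] < grid@dims[1] &
        ijk[, 2] >= 0 & ijk[, 2] < grid@dims[2] &
        ijk[, 3] >= 0 & ijk[, 3] < grid@dims[3]
  lin <- rep(NA_integer_, nrow(ijk))
  lin[ok] <- as.integer(ijk[ok, 1] + grid@dims[1] *
                          (ijk[ok, 2] + grid@dims[2] * ijk[ok, 3]) + 1)
  pos <- match(lin, grid@maskIdx)
  pos
}
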