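#' Read a 3-D volume into a VoxelMap
#'
#' The file must describe a volume on the same lattice as \code{grid}
#' (identical dimensions and voxel size); values are extracted at the
#' gray-mask voxels in the canonical ordering.
#'
#' @param path NIfTI-1 file.
#' @param grid the session \linkS4class{VoxelGrid}.
#' @return a \linkS4class{VoxelMap}.
#' @export
readVolume <- function(path, grid) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("could not parse volume: ",
                                           conditionMessage(e)))
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- arr[, , , 1L]
  if (!identical(as.integer(dim(arr)), grid@dims))
    stop("grid incompatibility: volume dimensions ",
         paste(dim(arr), collapse = "x"), " do not match the session grid")
  pd <- RNifti::pixdim(img)[1:3]
  if (any(abs(pd - grid@voxelSizeMm) > 1e-4))
    stop("grid incompatibility: voxel size differs from the session grid")
  VoxelMap(grid, as.numeric(arr[grid@maskIdx]))
}

#' Write a VoxelMap as a NIfTI-1 volume
#'
#' Non-gray voxels are written as 0.
#'
#' @param map a \linkS4class{VoxelMap}.
#' @param path output file path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
writeVolume <- function(map, path) {
  grid <- map@grid
  arr <- array(0, dim = grid@dims)
  arr[grid@maskIdx] <- map@values
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(grid@voxelSizeMm, 3)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read an analysis configuration file
#'
#' Thresholds and run parameters (correlation cutoff, distance cutoff,
#' alpha, cluster extent in mm^3, peak separation, permutation count,
#' seeds) are read from YAML or JSON and merged over the defaults from
#' \code{defaultHubConfig()}.
#'
#' @param path YAML (.yml/.yaml) or JSON (.json) file; \code{NULL} returns
#'   the defaults.
#' @return a named list.
#' @export
readHubConfig <- function(path = NULL) {
  cfg <- defaultHubConfig()
  if (is.null(path)) return(cfg)
  ext <- tolower(tools::file_ext(path))
  user <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("the 'jsonlite' package is required to read JSON configs")
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("unsupported config format: ", ext)
  utils::modifyList(cfg, user)
}

#' @rdname readHubConfig
#' @export
defaultHubConfig <- function() {
  list(
    rThreshold = 0.1,
    minDistanceMm = 20,
    excludeNegative = TRUE,
    alpha = 0.001,
    minClusterMm3 = 200,
    peakSeparationMm = 15,
    nPermutations = 10000L,
    seed = 1L
  )
}
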