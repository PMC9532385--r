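#' Accessor generics
#'
#' Small accessor layer so downstream code never touches slots directly.
#'
#' @param x an object.
#' @param ... further arguments for methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' @rdname accessors
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' @rdname accessors
#' @export
setGeneric("coordsMm", function(x) standardGeneric("coordsMm"))

#' @rdname accessors
#' @export
setGeneric("grayMask", function(x) standardGeneric("grayMask"))

#' @rdname accessors
#' @export
setGeneric("networkLabels", function(x, ...) standardGeneric("networkLabels"))

#' @rdname accessors
#' @export
setGeneric("voxelGrid", function(x) standardGeneric("voxelGrid"))

#' @rdname accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname accessors
#' @export
setGeneric("cohortId", function(x) standardGeneric("cohortId"))

#' @rdname accessors
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname accessors
#' @export
setGeneric("meanMap", function(x) standardGeneric("meanMap"))

#' @rdname accessors
#' @export
setGeneric("varianceMap", function(x) standardGeneric("varianceMap"))

#' @rdname accessors
#' @export
setGeneric("hubMask", function(x) standardGeneric("hubMask"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("hubPeaks", function(x) standardGeneric("hubPeaks"))

#' @rdname accessors
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' @rdname accessors
#' @export
setGeneric("surrogateValues", function(x) standardGeneric("surrogateValues"))

#' @rdname accessors
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname accessors
#' @export
setGeneric("sampleCoords", function(x) standardGeneric("sampleCoords"))

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
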