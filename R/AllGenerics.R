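#' @rdname Trajectory-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname Trajectory-accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname Trajectory-accessors
#' @export
setGeneric("timestamps", function(x) standardGeneric("timestamps"))

#' @rdname Trajectory-accessors
#' @export
setGeneric("topologyOf", function(x) standardGeneric("topologyOf"))

#' @rdname Trajectory-accessors
#' @export
setGeneric("frameCoords", function(x, frame = 1L) standardGeneric("frameCoords"))

#' @rdname Topology-accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname Topology-accessors
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))

#' @rdname CovarianceModel-accessors
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname CovarianceModel-accessors
#' @export
setGeneric("eigenvectors", function(x) standardGeneric("eigenvectors"))

#' @rdname ClusterModel-accessors
#' @export
setGeneric("clusterAssignment", function(x) standardGeneric("clusterAssignment"))

#' @rdname ClusterModel-accessors
#' @export
setGeneric("clusterPopulations", function(x) standardGeneric("clusterPopulations"))

#' @rdname ClusterModel-accessors
#' @export
setGeneric("referenceFrames", function(x) standardGeneric("referenceFrames"))

#' @rdname PreShape-accessors
#' @export
setGeneric("landmarks", function(x) standardGeneric("landmarks"))
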