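#' Trajectory accessors
#'
#' @param x a \linkS4class{Trajectory}.
#' @param frame 1-based frame index.
#' @return \code{nFrames}/\code{nAtoms} return integers; \code{timestamps}
#'   the per-frame times in ps; \code{frameCoords} the N x 3 coordinate
#'   matrix of one frame; \code{topologyOf} the \linkS4class{Topology}.
#' @name Trajectory-accessors
NULL

#' @rdname Trajectory-accessors
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[1])

#' @rdname Trajectory-accessors
#' @export
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[2])

#' @rdname Trajectory-accessors
#' @export
setMethod("nAtoms", "Topology", function(x) nrow(x@atoms))

#' @rdname Trajectory-accessors
#' @export
setMethod("timestamps", "Trajectory", function(x) x@timestamps)

#' @rdname Trajectory-accessors
#' @export
setMethod("topologyOf", "Trajectory", function(x) x@topology)

#' @rdname Trajectory-accessors
#' @export
setMethod("frameCoords", "Trajectory", function(x, frame = 1L) {
  stopifnot(frame >= 1L, frame <= dim(x@coords)[1])
  matrix(x@coords[frame, , ], ncol = 3,
         dimnames = list(NULL, c("x", "y", "z")))
})

#' Topology accessors
#'
#' @param x a \linkS4class{Topology}.
#' @return \code{atomTable} the atom data.frame; \code{residueTable} the
#'   residue data.frame.
#' @name Topology-accessors
NULL

#' @rdname Topology-accessors
#' @export
setMethod("atomTable", "Topology", function(x) x@atoms)

#' @rdname Topology-accessors
#' @export
setMethod("residueTable", "Topology", function(x) x@residues)

#' CovarianceModel accessors
#'
#' @param x a \linkS4class{CovarianceModel}.
#' @return eigenvalues (Angstrom^2, decreasing) or the matching
#'   eigenvector matrix; empty before [pcaModes()] has been applied.
#' @name CovarianceModel-accessors
NULL

#' @rdname CovarianceModel-accessors
#' @export
setMethod("eigenvalues", "CovarianceModel", function(x) x@evalues)

#' @rdname CovarianceModel-accessors
#' @export
setMethod("eigenvectors", "CovarianceModel", function(x) x@evectors)

#' ClusterModel accessors
#'
#' @param x a \linkS4class{ClusterModel}.
#' @return per-frame assignments, per-cluster populations (percent), or
#'   the reference frame ids.
#' @name ClusterModel-accessors
NULL

#' @rdname ClusterModel-accessors
#' @export
setMethod("clusterAssignment", "ClusterModel", function(x) x@assignment)

#' @rdname ClusterModel-accessors
#' @export
setMethod("clusterPopulations", "ClusterModel", function(x) x@populations)

#' @rdname ClusterModel-accessors
#' @export
setMethod("referenceFrames", "ClusterModel", function(x) x@refFrames)

#' PreShape accessors
#'
#' @param x a \linkS4class{PreShape}.
#' @return the k x 3 centred, unit-size landmark matrix.
#' @name PreShape-accessors
NULL

#' @rdname PreShape-accessors
#' @export
setMethod("landmarks", "PreShape", function(x) x@landmarks)

setMethod("show", "Topology", function(object) {
  cat(sprintf("Topology: %d atoms, %d residues, %d chain(s)\n",
              nrow(object@atoms), nrow(object@residues),
              length(unique(object@residues$chain))))
})

setMethod("show", "Trajectory", function(object) {
  d <- dim(object@coords)
  cat(sprintf("Trajectory: %d frame(s) x %d atoms, t = %g..%g ps\n",
              d[1], d[2], object@timestamps[1],
              object@timestamps[length(object@timestamps)]))
})

setMethod("show", "CovarianceModel", function(object) {
  cat(sprintf("CovarianceModel: %d coordinates (%d atoms), trace %.4g A^2",
              nrow(object@C), length(object@mask), sum(diag(object@C))))
  if (length(object@evalues))
    cat(sprintf(", top eigenvalue %.4g A^2", object@evalues[1]))
  cat("\n")
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: r = %.2f A, %d cluster(s) over %d frames\n",
              object@cutoff, length(object@refFrames),
              length(object@assignment)))
  cat("  populations (%):",
      paste(sprintf("%.1f", object@populations), collapse = ", "), "\n")
})

setMethod("show", "PreShape", function(object) {
  cat(sprintf("PreShape: %d landmarks (shape dimension %d)\n",
              nrow(object@landmarks), 3 * nrow(object@landmarks) - 7))
})
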